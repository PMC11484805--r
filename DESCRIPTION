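Package: lactnet
Title: Causal Networks and Recursive Structural Equation Models for
    Dairy Energy Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of energy-related blood
    metabolites (glucose, cholesterol, NEFA, BHB, urea) and daily milk
    energy output in dairy cows.  Provides a synthetic-herd generator
    with known genetic ground truth, single-step relationship matrices
    (pedigree A, genomic G, combined H), a multi-trait animal-model
    Gibbs sampler, score-based Bayesian-network structure learning on
    model residuals with bootstrap model averaging, and a recursive
    structural equation model sampler estimating structural path
    coefficients, heritabilities and genetic correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
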