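#' Assign herd, herd-date, parity and DIM to a set of cows
#'
#' Cows are spread uniformly over `n_herds` herds; each herd has
#' `dates_per_herd` sampling dates, giving `n_herds * dates_per_herd`
#' herd-date levels.  Parity is drawn from a decreasing distribution over
#' 1..4 and days in milk from a right-skewed distribution covering early
#' lactation through extended lactations (5-598 d).
#'
#' @param cow_ids Ids of the phenotyped cows.
#' @param n_herds Number of herds (default 5).
#' @param dates_per_herd Sampling dates per herd (default 4).
#' @param seed Optional RNG seed.
#' @return Tibble `animal`, `herd`, `herd_date`, `parity`, `dim`.
#' @export
simulate_design <- function(cow_ids, n_herds = 5, dates_per_herd = 4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(cow_ids)
  herd <- sample.int(n_herds, n, replace = TRUE)
  date <- sample.int(dates_per_herd, n, replace = TRUE)
  dim <- pmin(pmax(round(stats::rgamma(n, shape = 2.2, scale = 80)) + 5L, 5L), 598L)
  parity <- sample(1:4, n, replace = TRUE, prob = c(0.40, 0.30, 0.20, 0.10))
  tibble::tibble(
    animal = cow_ids,
    herd = herd,
    herd_date = (herd - 1L) * dates_per_herd + date,
    parity = parity,
    dim = as.integer(dim)
  )
}

#' Simulate recursive phenotypes with known ground truth
#'
#' Generates the six traits for the cows in `design` from the recursive
#' model y = (I - Lambda)^-1 (Xb + a + h + e) on the standardized scale.
#' Genetic values follow the pedigree by Mendelian-sampling recursion
#' (a_i = 0.5 a_sire + 0.5 a_dam + phi_i with phi_i ~ N(0, m_i Sigma_g)
#' and m_i the Mendelian-sampling scalar from the parents' inbreeding),
#' herd-date effects are iid N(0, Sigma_h), residuals independent across
#' cows and traits.  The standardized traits are then mapped to raw trait
#' units using the published population means and SDs, and milk
#' composition is generated so that energy output derived from
#' composition and yield reproduces the simulated dMEO.
#'
#' @param pedigree Pedigree tibble covering all cows in `design`.
#' @param design Output of [simulate_design()] (or same columns).
#' @param truth A `lact_ground_truth` object.
#' @param seed Optional RNG seed.
#' @return Phenotype tibble (one row per cow) with design columns, milk
#'   yield and composition, and the six raw-scale traits; attributes
#'   `latent` (standardized trait matrix) and `truth`.
#' @export
simulate_phenotypes <- function(pedigree, design, truth, seed = NULL) {
  if (!inherits(truth, "lact_ground_truth")) {
    rlang::abort("truth must be a lact_ground_truth", class = "lact_invalid_input")
  }
  ped <- validate_pedigree(pedigree)
  if (!all(design$animal %in% ped$animal)) {
    rlang::abort("design contains cows missing from the pedigree",
                 class = "lact_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  traits <- truth$traits
  t6 <- length(traits)
  n <- nrow(design)
  q <- nrow(ped)

  # genetic values by Mendelian-sampling recursion
  Lg <- t(chol(truth$sigma_g + diag(1e-10, t6)))
  pp <- ped_positions(ped)
  f <- c(-1, .inbreeding_ml(pp$sire, pp$dam))
  m <- 0.5 - 0.25 * (f[pp$sire + 1L] + f[pp$dam + 1L])
  a <- matrix(0, q, t6)
  Z <- matrix(stats::rnorm(q * t6), q, t6)
  for (i in seq_len(q)) {
    pa <- numeric(t6)
    if (pp$sire[i] > 0) pa <- pa + 0.5 * a[pp$sire[i], ]
    if (pp$dam[i] > 0) pa <- pa + 0.5 * a[pp$dam[i], ]
    a[i, ] <- pa + sqrt(m[i]) * as.numeric(Lg %*% Z[i, ])
  }

  lev <- sort(unique(design$herd_date))
  Lh <- t(chol(truth$sigma_h + diag(1e-10, t6)))
  h <- t(Lh %*% matrix(stats::rnorm(length(lev) * t6), t6))
  e <- matrix(stats::rnorm(n * t6), n, t6) %*% diag(sqrt(diag(truth$sigma_e)))

  dc <- dim_class(design$dim)
  pc <- parity_class(design$parity)
  xb <- truth$dim_effects[dc, , drop = FALSE] +
    truth$parity_effects[pc, , drop = FALSE]
  u <- xb + a[match(design$animal, ped$animal), , drop = FALSE] +
    h[match(design$herd_date, lev), , drop = FALSE] + e

  # forward substitution through (I - Lambda): traits are ordered so
  # every parent precedes its children
  y <- u
  for (j in seq_len(t6)) {
    prev <- which(truth$lambda[j, ] != 0)
    if (length(prev) > 0) {
      y[, j] <- u[, j] + y[, prev, drop = FALSE] %*% truth$lambda[j, prev]
    }
  }
  colnames(y) <- traits

  # raw-scale back-transformation
  st <- reference_trait_stats()
  rawv <- function(tr, z) {
    i <- match(tr, st$trait)
    st$mean[i] + st$sd[i] * z
  }
  dMEO_raw <- pmax(rawv("dMEO", y[, "dMEO"]), 5)
  fat <- pmax(rawv("fat_pct", stats::rnorm(n)), 0.5)
  protein <- pmax(rawv("protein_pct", stats::rnorm(n)), 1)
  lactose <- pmax(rawv("lactose_pct", stats::rnorm(n)), 2)
  nel <- compute_nel(fat, protein, lactose)

  out <- tibble::tibble(
    animal = design$animal,
    herd = design$herd,
    herd_date = design$herd_date,
    parity = design$parity,
    dim = design$dim,
    milk_yield = dMEO_raw / nel,
    fat_pct = fat,
    protein_pct = protein,
    lactose_pct = lactose,
    dMEO = dMEO_raw,
    glucose = rawv("glucose", y[, "glucose"]),
    CHOL = rawv("CHOL", y[, "CHOL"]),
    NEFA = rawv("NEFA", y[, "NEFA"]),
    BHB = rawv("BHB", y[, "BHB"]),
    urea = rawv("urea", y[, "urea"])
  )
  attr(out, "latent") <- y
  attr(out, "truth") <- truth
  out
}

#' Simulate a complete synthetic herd
#'
#' End-to-end generator: pedigree (founders plus `n_generations` bred
#' generations), SNP genotypes for a subset of the phenotyped cows,
#' design structure (herds, herd-dates, parity, DIM) and recursive
#' phenotypes from `truth`.  Phenotyped cows are the females of the last
#' two generations (emulating a milking herd spanning several parities);
#' the default sizes emulate the study population: ~1,250 cows in 5
#' herds, 20 herd-date levels.
#'
#' @param n_cows Number of phenotyped cows (default 1250).
#' @param n_herds,dates_per_herd Herd structure (defaults 5 and 4).
#' @param n_generations Bred generations (default 3).
#' @param n_snp Markers on the simulated panel (default 1000).
#' @param n_genotyped Phenotyped cows with genotypes (default 300).
#' @param truth Ground truth, default [default_ground_truth()].
#' @param missing_rate Missing-dosage rate injected into the genotypes.
#' @param seed Optional RNG seed controlling the whole herd.
#' @return A list of class `lact_herd` with elements `pedigree`,
#'   `genotypes`, `design`, `phenotypes`, `truth`, `cow_ids`.
#' @export
simulate_herd <- function(n_cows = 1250, n_herds = 5, dates_per_herd = 4,
                          n_generations = 3, n_snp = 1000, n_genotyped = 300,
                          truth = default_ground_truth(), missing_rate = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_founders <- ceiling(n_cows * 1.12) + 30
  ped <- simulate_pedigree(n_founders, n_generations)
  gmax <- max(ped$generation)
  cows <- ped$animal[ped$sex == "F" & ped$generation >= gmax - 1L]
  if (length(cows) < n_cows) {
    rlang::abort("pedigree produced too few candidate cows; increase n_cows margin",
                 class = "lact_invalid_configuration")
  }
  cows <- sort(sample(cows, n_cows))
  genotyped <- sort(sample(cows, min(n_genotyped, n_cows)))
  geno <- simulate_genotypes(ped, n_snp = n_snp, missing_rate = missing_rate)
  geno <- geno[as.character(genotyped), , drop = FALSE]
  design <- simulate_design(cows, n_herds = n_herds,
                            dates_per_herd = dates_per_herd)
  phen <- simulate_phenotypes(ped, design, truth)
  structure(list(
    pedigree = ped,
    genotypes = geno,
    design = design,
    phenotypes = phen,
    truth = truth,
    cow_ids = cows
  ), class = "lact_herd")
}

#' @exportS3Method base::print
print.lact_herd <- function(x, ...) {
  cat("Synthetic herd:", nrow(x$phenotypes), "cows,",
      nrow(x$pedigree), "pedigree records,",
      nrow(x$genotypes), "genotyped cows x", ncol(x$genotypes), "SNP\n")
  invisible(x)
}
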