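# shared fixtures built in code

# a fixed three-generation toy pedigree: founders 1-4, trio offspring
toy_pedigree <- function() {
  tibble::tibble(
    animal = 1:7,
    sire   = c(0L, 0L, 0L, 0L, 3L, 3L, 5L),
    dam    = c(0L, 0L, 0L, 0L, 1L, 2L, 6L),
    sex    = c("F", "F", "M", "M", "M", "F", "F"),
    generation = c(0L, 0L, 0L, 0L, 1L, 1L, 2L)
  )
}

# random valid pedigree of given size for property-style checks
random_pedigree <- function(n, seed) {
  simulate_pedigree(max(4, ceiling(n / 3)), 3,
                    offspring_per_mating = 2, seed = seed, n_sires = 3)
}

# small complete herd shared by sampler tests (cheap but non-trivial)
small_herd <- function(seed = 42, n_cows = 150) {
  simulate_herd(n_cows = n_cows, n_snp = 120, n_genotyped = 40,
                n_herds = 3, dates_per_herd = 3, seed = seed)
}

herd_model_inputs <- function(herd) {
  at <- build_analysis_table(herd$phenotypes, pedigree = herd$pedigree)
  ped <- prune_pedigree(herd$pedigree, at$animal, generations = 3)
  qc <- qc_genotypes(herd$genotypes)
  H_inv <- single_step_H_inverse(ped, impute_genotypes(qc$genotypes))
  list(at = at, ped = ped, H_inv = H_inv)
}

# exhaustive enumeration of all DAGs on a small node set (oracle for
# hill climbing): returns list of adjacency matrices
all_dags <- function(nodes) {
  k <- length(nodes)
  cells <- which(diag(k) == 0)
  out <- list()
  for (code in 0:(2^length(cells) - 1)) {
    amat <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
    bits <- bitwAnd(bitwShiftR(code, seq_along(cells) - 1), 1) == 1
    amat[cells[bits]] <- TRUE
    if (lactnet:::is_acyclic(amat)) out[[length(out) + 1]] <- amat
  }
  out
}

# direct (independent) Gaussian BIC evaluation via lm(), used as an
# oracle for the covariance-based local scores
bic_oracle <- function(m, amat) {
  n <- nrow(m)
  total <- 0
  for (j in seq_len(ncol(m))) {
    parents <- which(amat[, j])
    df <- data.frame(y = m[, j])
    rhs <- "1"
    if (length(parents) > 0) {
      for (s in seq_along(parents)) df[[paste0("x", s)]] <- m[, parents[s]]
      rhs <- paste(paste0("x", seq_along(parents)), collapse = " + ")
    }
    f <- stats::lm(stats::as.formula(paste("y ~", rhs)), df)
    s2 <- mean(stats::residuals(f)^2)
    ll <- -n / 2 * (log(2 * pi * s2) + 1)
    total <- total + ll - 0.5 * log(n) * (length(parents) + 2)
  }
  total
}
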