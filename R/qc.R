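#' Exact Hardy-Weinberg equilibrium test for one biallelic marker
#'
#' Conditional exact test on the heterozygote count given the allele
#' count (Wigginton et al. 2005).  The default mid-p variant halves the
#' probability of the observed configuration, which keeps the test close
#' to nominal size at low counts; a 1-df chi-square version is available.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (minor/major homozygotes and
#'   heterozygotes in any orientation).
#' @param method `"midp"` (default), `"exact"` or `"chisq"`.
#' @return P-value.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("midp", "exact", "chisq")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  if (method == "chisq") {
    p <- (2 * n_aa + n_ab) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # rare allele count
  na <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  h_obs <- n_ab
  h_max <- min(na, 2 * n - na)
  h_min <- na %% 2
  hs <- seq(h_min, h_max, by = 2)
  # unnormalized log-probabilities via the ratio
  # p(h+2) = p(h) * (na-h)(2n-na-h) / ((h+2)(h+1))
  logp <- numeric(length(hs))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    logp[k] <- logp[k - 1] +
      log(na - h) + log(2 * n - na - h) - log(h + 2) - log(h + 1)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(h_obs, hs)]
  if (is.na(p_obs)) return(0)
  eps <- 1e-12
  less <- p < p_obs - eps
  equal <- abs(p - p_obs) <= eps
  if (method == "exact") sum(p[less | equal]) else sum(p[less]) + 0.5 * sum(p[equal])
}

#' Genotype quality control
#'
#' Single-pass marker filters, then a sample filter: markers are removed
#' for minor allele frequency below `maf_min`, exact-test departure from
#' Hardy-Weinberg equilibrium at `P <= hwe_p_min`, or marker call rate
#' below `call_rate_min` (each removed marker is attributed to the first
#' failing filter, in that order); afterwards samples with call rate
#' below `call_rate_min` over the retained markers are removed.
#'
#' @param genotypes Dosage matrix (animals x markers, 0/1/2/NA).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Markers with HWE p <= this are removed (default 1e-5).
#' @param call_rate_min Minimum call rate for markers and samples
#'   (default 0.95).
#' @param hwe_method Test flavour passed to [hwe_test()].
#' @return A list with `genotypes` (the filtered matrix) and `report`
#'   (class `lact_qc_report`).
#' @export
qc_genotypes <- function(genotypes, maf_min = 0.05, hwe_p_min = 1e-5,
                         call_rate_min = 0.95, hwe_method = "midp") {
  M <- as.matrix(genotypes)
  if (nrow(M) == 0 || ncol(M) == 0) {
    rlang::abort("empty dosage matrix", class = "lact_invalid_input")
  }
  n_markers_in <- ncol(M)
  n_samples_in <- nrow(M)

  called <- !is.na(M)
  marker_cr <- colMeans(called)
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(M)), function(j) {
    x <- M[called[, j], j]
    hwe_test(sum(x == 2), sum(x == 1), sum(x == 0), method = hwe_method)
  }, numeric(1))

  fail_maf <- maf < maf_min
  fail_hwe <- !fail_maf & hwe_p <= hwe_p_min
  fail_cr <- !fail_maf & !fail_hwe & marker_cr < call_rate_min
  keep_marker <- !(fail_maf | fail_hwe | fail_cr)

  M2 <- M[, keep_marker, drop = FALSE]
  if (ncol(M2) > 0) {
    sample_cr <- rowMeans(!is.na(M2))
  } else {
    sample_cr <- rep(0, nrow(M2))
  }
  keep_sample <- sample_cr >= call_rate_min
  M3 <- M2[keep_sample, , drop = FALSE]

  report <- structure(list(
    n_markers_in = n_markers_in,
    n_samples_in = n_samples_in,
    removed_maf = sum(fail_maf),
    removed_hwe = sum(fail_hwe),
    removed_marker_call_rate = sum(fail_cr),
    removed_sample_call_rate = sum(!keep_sample),
    n_markers_retained = ncol(M3),
    n_samples_retained = nrow(M3),
    thresholds = list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                      call_rate_min = call_rate_min, hwe_method = hwe_method)
  ), class = "lact_qc_report")

  if (ncol(M3) == 0) {
    rlang::abort("all markers removed by QC", class = "lact_empty_result",
                 report = report)
  }
  list(genotypes = M3, report = report)
}

#' @exportS3Method base::print
print.lact_qc_report <- function(x, ...) {
  cat("Genotype QC:", x$n_markers_in, "markers x", x$n_samples_in, "samples\n")
  cat("  removed: MAF", x$removed_maf, "| HWE", x$removed_hwe,
      "| marker call rate", x$removed_marker_call_rate,
      "| samples", x$removed_sample_call_rate, "\n")
  cat("  retained:", x$n_markers_retained, "markers x",
      x$n_samples_retained, "samples\n")
  invisible(x)
}

#' Mean-impute missing dosages per marker
#'
#' @param genotypes Dosage matrix with possible NA entries.
#' @return Numeric matrix with NA replaced by the marker mean.
#' @export
impute_genotypes <- function(genotypes) {
  M <- as.matrix(genotypes) * 1.0
  if (!anyNA(M)) return(M)
  mm <- colMeans(M, na.rm = TRUE)
  mm[is.nan(mm)] <- 0
  idx <- which(is.na(M), arr.ind = TRUE)
  M[idx] <- mm[idx[, 2]]
  M
}
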