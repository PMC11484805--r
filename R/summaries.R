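#' Highest posterior density interval (empirical shortest window)
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' computed by sliding a fixed-size window over the sorted draws
#' (Chen-Shao).  The window spans `round(n * mass)` gaps (so
#' `round(n * mass) + 1` order statistics); among equal-width windows the
#' leftmost is returned, which makes the result deterministic.
#'
#' @param draws Numeric vector of posterior draws (at least 50).
#' @param mass Interval mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 50) {
    rlang::abort("at least 50 draws required for an HPD interval",
                 class = "lact_insufficient_sample")
  }
  if (mass <= 0 || mass >= 1) {
    rlang::abort("mass must be in (0, 1)", class = "lact_invalid_input")
  }
  x <- sort(draws)
  gap <- max(1L, min(n - 1L, round(n * mass)))
  starts <- seq_len(n - gap)
  widths <- x[starts + gap] - x[starts]
  i <- which.min(widths) # which.min takes the first (leftmost) minimum
  c(lower = x[i], upper = x[i + gap])
}

#' Sign probability of a posterior distribution
#'
#' Probability (in percent) that the parameter shares the sign of its
#' posterior mean: the fraction of draws above 0 when the mean is
#' positive, below 0 when negative.  Estimates with P >= 95 are flagged
#' "relevant" downstream.
#'
#' @param draws Numeric vector of posterior draws.
#' @return P in \[0, 100\].
#' @export
sign_probability <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) == 0) {
    rlang::abort("draws must be non-empty", class = "lact_invalid_input")
  }
  if (mean(draws) > 0) 100 * mean(draws > 0) else 100 * mean(draws < 0)
}

#' Summarise columns of posterior draws
#'
#' @param draws A numeric matrix (draws in rows) or data frame of
#'   posterior draws, one parameter per column.
#' @param mass HPD mass, default 0.95.
#' @param relevance_threshold Sign-probability percentage above which an
#'   estimate is flagged relevant (default 95).
#' @return A tibble with one row per parameter: `parameter`, `mean`,
#'   `hpd_lower`, `hpd_upper`, `P`, `relevant`.
#' @export
posterior_summary <- function(draws, mass = 0.95, relevance_threshold = 95) {
  m <- as.matrix(draws)
  if (is.null(colnames(m))) colnames(m) <- paste0("par", seq_len(ncol(m)))
  rows <- lapply(colnames(m), function(p) {
    d <- m[, p]
    h <- hpd_interval(d, mass)
    P <- sign_probability(d)
    tibble::tibble(parameter = p, mean = mean(d),
                   hpd_lower = unname(h[1]), hpd_upper = unname(h[2]),
                   P = P, relevant = P >= relevance_threshold)
  })
  dplyr::bind_rows(rows)
}

#' Effective sample size of an MCMC chain
#'
#' Initial-positive-sequence estimator: the integrated autocorrelation time
#' is accumulated over pairs of consecutive autocorrelations until a pair
#' sums to a non-positive value (Geyer).  Used for convergence reporting.
#'
#' @param x Numeric vector of (thinned) draws.
#' @return Estimated effective sample size.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(as.numeric(n))
  max_lag <- min(n - 2L, 200L)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  tau <- 1
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  min(n, n / tau)
}
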