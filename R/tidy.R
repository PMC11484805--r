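#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

fit_param_summary <- function(fit, parameter) {
  pars <- derive_genetic_parameters(fit)
  out <- switch(parameter,
    heritability = posterior_summary(pars$h2),
    genetic_correlation = posterior_summary(pars$r_g),
    residual_correlation = {
      if (is.null(pars$r_e)) {
        return(tibble::tibble(parameter = character(), mean = numeric(),
                              hpd_lower = numeric(), hpd_upper = numeric(),
                              P = numeric(), relevant = logical()))
      }
      posterior_summary(pars$r_e)
    },
    path = {
      if (is.null(fit$lambda_draws) || ncol(fit$lambda_draws) == 0) {
        return(tibble::tibble(parameter = character(), mean = numeric(),
                              hpd_lower = numeric(), hpd_upper = numeric(),
                              P = numeric(), relevant = logical()))
      }
      posterior_summary(fit$lambda_draws)
    },
    rlang::abort(paste("unknown parameter type", parameter))
  )
  out
}

#' Tidy posterior summaries of a multi-trait animal-model fit
#'
#' One row per heritability and per genetic/residual correlation, with
#' posterior mean, HPD95% bounds, sign probability P (percent) and the
#' relevance flag (P >= 95).
#'
#' @param x A `lact_mtm_fit`.
#' @param parameter Which block to return: `"all"` (default),
#'   `"heritability"`, `"genetic_correlation"`,
#'   `"residual_correlation"`.
#' @param ... Unused.
#' @return A tibble with a `type` column and the summary columns of
#'   [posterior_summary()].
#' @export
tidy.lact_mtm_fit <- function(x, parameter = "all", ...) {
  types <- c("heritability", "genetic_correlation", "residual_correlation")
  if (!identical(parameter, "all")) types <- match.arg(parameter, types)
  dplyr::bind_rows(lapply(types, function(tp) {
    s <- fit_param_summary(x, tp)
    if (nrow(s) > 0) s$type <- tp
    s
  })) %>% dplyr::select(dplyr::any_of(c("type", "parameter", "mean",
                                        "hpd_lower", "hpd_upper", "P",
                                        "relevant")))
}

#' Tidy posterior summaries of a recursive SEM fit
#'
#' @param x A `lact_sem_fit`.
#' @param parameter `"all"` (default), `"path"` (structural
#'   coefficients), `"heritability"` or `"genetic_correlation"`.
#' @param ... Unused.
#' @return A tibble as in [tidy.lact_mtm_fit()], with structural paths
#'   labelled `"from->to"`.
#' @export
tidy.lact_sem_fit <- function(x, parameter = "all", ...) {
  types <- c("path", "heritability", "genetic_correlation")
  if (!identical(parameter, "all")) types <- match.arg(parameter, types)
  dplyr::bind_rows(lapply(types, function(tp) {
    s <- fit_param_summary(x, tp)
    if (nrow(s) > 0) s$type <- tp
    s
  })) %>% dplyr::select(dplyr::any_of(c("type", "parameter", "mean",
                                        "hpd_lower", "hpd_upper", "P",
                                        "relevant")))
}

glance_fit <- function(x) {
  pars <- derive_genetic_parameters(x)
  ess <- apply(pars$h2, 2, effective_sample_size)
  tibble::tibble(
    n = x$n, n_draws = x$n_keep,
    n_iter = x$config$n_iter, burn_in = x$config$burn_in,
    thin = x$config$thin,
    min_ess_h2 = min(ess), median_ess_h2 = stats::median(ess)
  )
}

#' One-row chain diagnostics
#'
#' @param x A fitted model object.
#' @param ... Unused.
#' @return Tibble with data size, chain settings and effective sample
#'   sizes of the heritability chains.
#' @export
glance.lact_mtm_fit <- function(x, ...) glance_fit(x)

#' @rdname glance.lact_mtm_fit
#' @export
glance.lact_sem_fit <- function(x, ...) glance_fit(x)

#' Tidy edge table of a bootstrap-averaged network
#'
#' @param x A `lact_avg_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `strength`, `direction`) with
#'   a `retained` flag.
#' @export
tidy.lact_avg_network <- function(x, ...) {
  e <- x$edges
  e$retained <- !is.na(e$direction) & e$strength >= x$threshold &
    e$direction > 0.5
  e
}
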