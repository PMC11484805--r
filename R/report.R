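#' Assemble a posterior report from the fitted stages
#'
#' Bundles (i) the multi-trait results as a trait-by-trait table with
#' heritabilities on the diagonal, genetic correlations above and
#' residual correlations below; (ii) the structural-path table
#' (posterior mean, HPD95%, P, relevance); (iii) the SEM genetic
#' parameters; (iv) the averaged-network edge table.  Stages not yet run
#' may be `NULL`: the report covers what is available and records a
#' `partial` flag.
#'
#' @param mtm_fit A `lact_mtm_fit` (or `NULL`).
#' @param sem_fit A `lact_sem_fit` (or `NULL`).
#' @param network A `lact_avg_network` (or `NULL`).
#' @return Object of class `lact_report`: a list of tibbles/matrices.
#' @export
assemble_report <- function(mtm_fit = NULL, sem_fit = NULL, network = NULL) {
  partial <- is.null(mtm_fit) || is.null(sem_fit) || is.null(network)
  if (partial) warning("partial report: not all stages provided")
  rep <- list(partial = partial)
  if (!is.null(mtm_fit)) {
    rep$mtm <- tidy(mtm_fit)
    rep$mtm_matrix <- correlation_matrix_table(mtm_fit)
  }
  if (!is.null(sem_fit)) {
    rep$sem <- tidy(sem_fit)
    rep$paths <- tidy(sem_fit, parameter = "path")
    rep$sem_matrix <- correlation_matrix_table(sem_fit)
  }
  if (!is.null(network)) {
    rep$network <- tidy(network)
  }
  structure(rep, class = "lact_report")
}

# square display table: h2 on the diagonal, genetic correlations above,
# residual correlations below (blank for diagonal-residual fits)
correlation_matrix_table <- function(fit) {
  traits <- fit$traits
  t6 <- length(traits)
  pars <- derive_genetic_parameters(fit)
  fmt <- function(draws) {
    s <- posterior_summary(as.matrix(draws))
    sprintf("%.3f (P=%.0f)", s$mean, s$P)
  }
  M <- matrix("", t6, t6, dimnames = list(traits, traits))
  h <- posterior_summary(pars$h2)
  diag(M) <- sprintf("%.3f [%.2f, %.2f]", h$mean, h$hpd_lower, h$hpd_upper)
  pair <- which(upper.tri(matrix(0, t6, t6)), arr.ind = TRUE)
  rg <- fmt(pars$r_g)
  for (k in seq_len(nrow(pair))) M[pair[k, 1], pair[k, 2]] <- rg[k]
  if (!is.null(pars$r_e)) {
    re <- fmt(pars$r_e)
    for (k in seq_len(nrow(pair))) M[pair[k, 2], pair[k, 1]] <- re[k]
  }
  M
}

#' @exportS3Method base::print
print.lact_report <- function(x, ...) {
  cat("lactnet report", if (x$partial) "(partial)" else "", "\n")
  if (!is.null(x$mtm_matrix)) {
    cat("\nMulti-trait model (diagonal: h2 [HPD95%]; above: r_g; below: r_e)\n")
    print(x$mtm_matrix, quote = FALSE)
  }
  if (!is.null(x$paths) && nrow(x$paths) > 0) {
    cat("\nStructural coefficients\n")
    print(as.data.frame(x$paths))
  }
  if (!is.null(x$network)) {
    kept <- x$network[x$network$retained, ]
    cat("\nRetained network edges:", nrow(kept), "\n")
  }
  invisible(x)
}

#' Write a report to disk as CSV tables and a JSON bundle
#'
#' @param report A `lact_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mtm", "sem", "paths", "network")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(as.data.frame(report[[nm]]),
                       file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  json <- unclass(report)
  json$mtm_matrix <- NULL
  json$sem_matrix <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       digits = NA, dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
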