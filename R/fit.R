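#' Configuration of a Gibbs chain
#'
#' Desk-scale defaults (20,000 iterations, 2,000 burn-in, thinning 10)
#' keep a full analysis within minutes on one core; the `"full"`
#' profile switches to the full-scale protocol (500,000 / 50,000 /
#' thinning 100).  Priors are weakly informative: inverse-Wishart with
#' `nu0 = t + 2` degrees of freedom and scale `prior_scale * I` for each
#' covariance matrix on the standardized trait scale, scaled
#' inverse-chi-square (`nu0_e`, `s0_e`) for per-trait residual variances
#' in diagonal-residual models, flat priors for location effects.
#'
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning.
#' @param seed RNG seed for the chain (set for reproducibility).
#' @param nu0 Prior degrees of freedom for the inverse-Wishart updates.
#' @param prior_scale Scalar multiplying the identity prior scale matrix.
#' @param nu0_e,s0_e Prior degrees of freedom and scale sum for
#'   diagonal residual variances.
#' @param store_residual_draws Keep the full per-draw residual matrices
#'   (memory-hungry; used for pooled-residual network learning).
#' @param profile `"desk"` (default) or `"full"`; overrides the chain
#'   length arguments.
#' @return A list of class `lact_chain_config`.
#' @export
chain_config <- function(n_iter = 20000, burn_in = 2000, thin = 10,
                         seed = NULL, nu0 = 8, prior_scale = 0.5,
                         nu0_e = 4, s0_e = 0.5,
                         store_residual_draws = FALSE,
                         profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    n_iter <- 500000; burn_in <- 50000; thin <- 100
  }
  if (burn_in >= n_iter || thin < 1) {
    rlang::abort("burn_in must be below n_iter and thin >= 1",
                 class = "lact_invalid_configuration")
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, nu0 = nu0, prior_scale = prior_scale,
                 nu0_e = nu0_e, s0_e = s0_e,
                 store_residual_draws = store_residual_draws,
                 profile = profile),
            class = "lact_chain_config")
}

# Assemble design pieces shared by both samplers
model_frame <- function(analysis_table, H_inv, traits) {
  at <- analysis_table
  Y <- as.matrix(at[, traits])
  df <- data.frame(
    dim_class = droplevels(at$dim_class),
    parity_class = droplevels(at$parity_class)
  )
  # corner-point parameterization: intercept plus dummies for all but the
  # first observed level; single-level factors drop out entirely
  terms <- names(df)[vapply(df, nlevels, 1L) >= 2]
  fml <- if (length(terms) == 0) ~1 else
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  hd <- droplevels(factor(at$herd_date))
  animal <- match(as.character(at$animal), rownames(H_inv))
  if (anyNA(animal)) {
    rlang::abort("analysis table contains animals missing from H_inv",
                 class = "lact_id_mismatch")
  }
  list(Y = Y, X = X, herd = as.integer(hd), n_herd = nlevels(hd),
       herd_levels = levels(hd), animal = as.integer(animal))
}

fit_core <- function(analysis_table, H_inv, config, sem, pattern, order,
                     resid_mode, fixed_covariances = NULL) {
  traits <- order
  mf <- model_frame(analysis_table, H_inv, traits)
  t6 <- length(traits)
  S0 <- diag(config$prior_scale, t6)
  if (is.null(fixed_covariances)) {
    Sg_init <- diag(0.2, t6); Sh_init <- diag(0.1, t6); Se_init <- diag(0.7, t6)
    upd <- c(g = TRUE, h = TRUE, e = resid_mode != 2)
  } else {
    Sg_init <- as.matrix(fixed_covariances$sigma_g)
    Sh_init <- if (!is.null(fixed_covariances$sigma_h)) {
      as.matrix(fixed_covariances$sigma_h)
    } else diag(1e-6, t6)
    Se_init <- as.matrix(fixed_covariances$sigma_e)
    upd <- c(g = FALSE, h = FALSE, e = FALSE)
  }
  if (resid_mode == 2) Se_init <- diag(1, t6)
  if (!is.null(config$seed)) set.seed(config$seed)
  Hs <- methods::as(methods::as(H_inv, "generalMatrix"), "CsparseMatrix")
  res <- .gibbs_core(
    mf$Y, mf$X, mf$herd, mf$n_herd, mf$animal, Hs,
    matrix(as.integer(pattern), t6, t6), sem, as.integer(resid_mode),
    config$n_iter, config$burn_in, config$thin,
    config$nu0, S0, S0, S0, config$nu0_e, config$s0_e,
    upd["g"], upd["h"], upd["e"],
    Sg_init, Sh_init, Se_init, isTRUE(config$store_residual_draws)
  )
  res$traits <- traits
  res$mf <- mf
  res
}

cov_colnames <- function(traits) {
  as.vector(outer(traits, traits, function(a, b) paste(a, b, sep = ":")))
}

#' Fit the Bayesian multi-trait animal model
#'
#' Gibbs sampler for y = Xb + Wg + Zh + e with six standardized traits,
#' fixed DIM-class and parity-class effects, a random herd-date effect
#' (h ~ N(0, I x Sigma_h)) and an additive genetic effect with combined
#' pedigree-genomic kinship (g ~ N(0, H x Sigma_g)).  All three
#' covariance matrices are unstructured by default.  Location effects
#' are sampled blockwise per effect level across traits; covariances by
#' inverse-Wishart full conditionals.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @param H_inv Sparse inverse relationship matrix covering all animals
#'   in the table (see [single_step_H_inverse()]).
#' @param config A [chain_config()].
#' @param resid `"unstructured"` (default), `"diagonal"` or
#'   `"identity"` residual covariance.
#' @param fixed_covariances Optional list (`sigma_g`, `sigma_h`,
#'   `sigma_e`) freezing the covariance matrices (no covariance updates;
#'   used for validation against closed-form solutions).
#' @return Object of class `lact_mtm_fit`.
#' @export
run_mtm <- function(analysis_table, H_inv, config = chain_config(),
                    resid = c("unstructured", "diagonal", "identity"),
                    fixed_covariances = NULL) {
  resid <- match.arg(resid)
  resid_mode <- match(resid, c("unstructured", "diagonal", "identity")) - 1L
  traits <- intersect(lact_traits(), colnames(analysis_table))
  res <- fit_core(analysis_table, H_inv, config, sem = FALSE,
                  pattern = matrix(0L, length(traits), length(traits)),
                  order = traits, resid_mode = resid_mode,
                  fixed_covariances = fixed_covariances)
  new_fit(res, analysis_table, config, class = "lact_mtm_fit",
          resid = resid, causal = NULL)
}

#' Fit the recursive structural equation model
#'
#' Gibbs sampler for y = (Lambda x I) y + Xb + Wa + Zh + e: the
#' multi-trait animal model augmented, per trait, with its parent
#' traits' observed phenotypes as covariates whose coefficients are the
#' structural coefficients lambda.  Residuals are independent across
#' traits (diagonal covariance with free variances by default;
#' `resid = "identity"` fixes them to 1 for the strict identity
#' constraint).  Genetic and herd-date (co)variances are sampled as in
#' [run_mtm()].
#'
#' @inheritParams run_mtm
#' @param structure A `lact_causal_structure` from
#'   [to_causal_structure()], giving the trait order and the recursive
#'   path pattern.
#' @param resid `"diagonal"` (default) or `"identity"`.
#' @return Object of class `lact_sem_fit`, with per-draw structural
#'   coefficients in `lambda_draws` (columns named `"from->to"`).
#' @export
run_sem <- function(analysis_table, H_inv, structure,
                    config = chain_config(),
                    resid = c("diagonal", "identity"),
                    fixed_covariances = NULL) {
  resid <- match.arg(resid)
  if (!inherits(structure, "lact_causal_structure")) {
    rlang::abort("structure must be a lact_causal_structure",
                 class = "lact_invalid_configuration")
  }
  if (!setequal(structure$order, intersect(lact_traits(), colnames(analysis_table)))) {
    rlang::abort("structure traits do not match the analysis table",
                 class = "lact_invalid_configuration")
  }
  resid_mode <- if (resid == "diagonal") 1L else 2L
  res <- fit_core(analysis_table, H_inv, config, sem = TRUE,
                  pattern = structure$pattern * 1L,
                  order = structure$order, resid_mode = resid_mode,
                  fixed_covariances = fixed_covariances)
  fit <- new_fit(res, analysis_table, config, class = "lact_sem_fit",
                 resid = resid, causal = structure)
  # name the lambda columns from the stored pattern (parents ascending
  # within each trait, matching the sampler's storage order)
  nm <- character(0)
  ord <- structure$order
  for (j in seq_along(ord)) {
    for (i in which(structure$pattern[j, ])) {
      nm <- c(nm, paste0(ord[i], "->", ord[j]))
    }
  }
  if (res$n_paths > 0) {
    fit$lambda_draws <- res$lambda[, seq_along(nm), drop = FALSE]
    colnames(fit$lambda_draws) <- nm
  } else {
    fit$lambda_draws <- matrix(numeric(0), nrow = res$n_keep, ncol = 0)
  }
  fit
}

new_fit <- function(res, analysis_table, config, class, resid, causal) {
  traits <- res$traits
  cn <- cov_colnames(traits)
  colnames(res$sigma_g) <- cn
  colnames(res$sigma_h) <- cn
  colnames(res$sigma_e) <- cn
  resid_mean <- res$resid_mean
  colnames(resid_mean) <- traits
  rownames(resid_mean) <- as.character(analysis_table$animal)
  out <- list(
    traits = traits,
    sigma_g_draws = res$sigma_g,
    sigma_h_draws = res$sigma_h,
    sigma_e_draws = res$sigma_e,
    b_draws = res$b,
    h_draws = res$h,
    resid_mean = resid_mean,
    resid_draws = res$resid_draws,
    a_mean = res$a_mean,
    n_keep = res$n_keep,
    n = nrow(analysis_table),
    resid = resid,
    structure = causal,
    config = config,
    scaling = attr(analysis_table, "scaling")
  )
  structure(out, class = c(class, "lact_fit"))
}

#' @exportS3Method base::print
print.lact_fit <- function(x, ...) {
  cat(class(x)[1], ": ", x$n, " cows, ", length(x$traits), " traits, ",
      x$n_keep, " retained draws (", x$config$n_iter, " iterations)\n",
      sep = "")
  invisible(x)
}

#' Posterior residuals of a fitted model
#'
#' @param fit A `lact_mtm_fit` or `lact_sem_fit`.
#' @param type `"mean"` (posterior-mean residual per cow and trait,
#'   default) or `"draws"` (per-draw residual matrices, available when
#'   the chain was run with `store_residual_draws = TRUE`).
#' @return An n x t matrix, or an n x t x draws array for `"draws"`.
#' @export
extract_residuals <- function(fit, type = c("mean", "draws")) {
  type <- match.arg(type)
  if (type == "mean") return(fit$resid_mean)
  if (is.null(fit$resid_draws)) {
    rlang::abort("chain was not run with store_residual_draws = TRUE",
                 class = "lact_invalid_input")
  }
  fit$resid_draws
}

#' Per-draw heritabilities and genetic/residual correlations
#'
#' Heritability divides the additive genetic variance by the sum of
#' genetic, herd-date and residual variances; correlations are the usual
#' covariance-to-correlation conversions, applied draw by draw.
#'
#' @param fit A fitted model object.
#' @return List of draw matrices: `h2` (draws x traits), `r_g` and
#'   `r_e` (draws x trait pairs, columns `"a:b"`); `r_e` is `NULL` for
#'   diagonal-residual fits.
#' @export
derive_genetic_parameters <- function(fit) {
  traits <- fit$traits
  t6 <- length(traits)
  dg <- diag_idx(t6)
  Sg <- fit$sigma_g_draws
  Sh <- fit$sigma_h_draws
  Se <- fit$sigma_e_draws
  vg <- Sg[, dg, drop = FALSE]
  vh <- Sh[, dg, drop = FALSE]
  ve <- Se[, dg, drop = FALSE]
  h2 <- vg / (vg + vh + ve)
  colnames(h2) <- traits
  pair <- which(upper.tri(matrix(0, t6, t6)), arr.ind = TRUE)
  pair_names <- paste(traits[pair[, 1]], traits[pair[, 2]], sep = ":")
  corr_mat <- function(S, v) {
    out <- sapply(seq_len(nrow(pair)), function(k) {
      i <- pair[k, 1]; j <- pair[k, 2]
      S[, (j - 1) * t6 + i] / sqrt(v[, i] * v[, j])
    })
    out <- matrix(out, ncol = nrow(pair))
    colnames(out) <- pair_names
    out
  }
  r_g <- corr_mat(Sg, vg)
  r_e <- if (fit$resid == "unstructured") corr_mat(Se, ve) else NULL
  list(h2 = h2, r_g = r_g, r_e = r_e)
}

diag_idx <- function(t6) (seq_len(t6) - 1) * t6 + seq_len(t6)

#' Reduced-form covariances implied by a recursive model
#'
#' Applies the transformation (I - Lambda)^-1 S (I - Lambda)^-T to each
#' covariance component: the covariances a standard multi-trait model
#' would estimate when the data follow the recursive model.
#'
#' @param sigma_g,sigma_h,sigma_e Structural-scale covariance matrices.
#' @param lambda Strictly lower-triangular structural coefficients.
#' @return List with the transformed `sigma_g`, `sigma_h`, `sigma_e`.
#' @export
reduced_form <- function(sigma_g, sigma_h, sigma_e, lambda) {
  t6 <- nrow(lambda)
  if (any(lambda[upper.tri(lambda, diag = TRUE)] != 0)) {
    rlang::abort("lambda must be strictly lower triangular",
                 class = "lact_invalid_input")
  }
  Tm <- solve(diag(t6) - lambda)
  tf <- function(S) Tm %*% as.matrix(S) %*% t(Tm)
  list(sigma_g = tf(sigma_g), sigma_h = tf(sigma_h), sigma_e = tf(sigma_e))
}
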