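test_that("reduced form applies the recursive transformation", {
  truth <- default_ground_truth()
  # no recursion: identity transformation
  rf0 <- reduced_form(truth$sigma_g, truth$sigma_h, truth$sigma_e,
                      matrix(0, 6, 6))
  expect_equal(rf0$sigma_g, truth$sigma_g, ignore_attr = TRUE)
  # random dense oracle
  set.seed(1)
  for (rep in 1:3) {
    L <- matrix(0, 6, 6)
    L[lower.tri(L)] <- rnorm(15, sd = 0.3)
    S <- crossprod(matrix(rnorm(36), 6)) + diag(0.2, 6)
    rf <- reduced_form(S, diag(6), diag(6), L)
    Tm <- solve(diag(6) - L)
    expect_equal(rf$sigma_g, Tm %*% S %*% t(Tm), tolerance = 1e-12)
  }
  Lb <- matrix(0, 6, 6); Lb[1, 2] <- 0.1
  expect_error(reduced_form(diag(6), diag(6), diag(6), Lb),
               class = "lact_invalid_input")
})

test_that("a single strong path is recovered without genetic effects", {
  # only glucose -> BHB active, lambda = 0.5, negligible genetics:
  # the SEM posterior must land within 3 posterior SDs of the truth
  truth <- default_ground_truth()
  L <- matrix(0, 6, 6, dimnames = list(lact_traits(), lact_traits()))
  L["BHB", "glucose"] <- 0.5
  t0 <- ground_truth(L, diag(1e-8, 6), diag(0.05, 6), diag(0.9, 6),
                     truth$dim_effects, truth$parity_effects)
  n <- 2000
  ped <- simulate_pedigree(n, 0)
  des <- simulate_design(ped$animal, seed = 2)
  ph <- simulate_phenotypes(ped, des, t0, seed = 3)
  at <- build_analysis_table(ph)
  struct <- to_causal_structure(
    tibble::tibble(from = "glucose", to = "BHB"))
  fit <- run_sem(at, build_A_inverse(ped), struct,
                 chain_config(n_iter = 1500, burn_in = 500, thin = 2,
                              seed = 4))
  s <- posterior_summary(fit$lambda_draws)
  expect_identical(s$parameter, "glucose->BHB")
  psd <- sd(fit$lambda_draws[, 1])
  expect_lt(abs(s$mean - 0.5), 3 * psd)
  expect_true(s$relevant)
})

test_that("the empty-structure SEM agrees with the diagonal-residual MTM", {
  herd <- small_herd(seed = 31, n_cows = 150)
  inp <- herd_model_inputs(herd)
  cfg <- function(seed) chain_config(n_iter = 8000, burn_in = 2000,
                                     thin = 3, seed = seed)
  empty <- to_causal_structure(new_dag(lact_traits()))
  fs <- run_sem(inp$at, inp$H_inv, empty, cfg(5))
  fm <- run_mtm(inp$at, inp$H_inv, cfg(6), resid = "diagonal")
  expect_equal(ncol(fs$lambda_draws), 0)
  hs <- colMeans(derive_genetic_parameters(fs)$h2)
  hm <- colMeans(derive_genetic_parameters(fm)$h2)
  # same posterior, different blocking: agreement within Monte-Carlo error
  expect_lt(max(abs(hs - hm)), 0.06)
  es <- colMeans(fs$sigma_e_draws[, lactnet:::diag_idx(6)])
  em <- colMeans(fm$sigma_e_draws[, lactnet:::diag_idx(6)])
  expect_lt(max(abs(es - em)), 0.06)
})

test_that("identity-residual mode keeps the residual variances fixed", {
  herd <- small_herd(seed = 32, n_cows = 100)
  inp <- herd_model_inputs(herd)
  struct <- to_causal_structure(default_path_table())
  fit <- run_sem(inp$at, inp$H_inv, struct,
                 chain_config(n_iter = 300, burn_in = 100, thin = 2, seed = 7),
                 resid = "identity")
  expect_true(all(fit$sigma_e_draws[, lactnet:::diag_idx(6)] == 1))
  # per-draw parameter bounds hold on every retained draw
  pars <- derive_genetic_parameters(fit)
  expect_true(all(pars$h2 >= 0 & pars$h2 <= 1))
  expect_true(all(abs(pars$r_g) <= 1))
})

test_that("structure and table must describe the same traits", {
  herd <- small_herd(seed = 33, n_cows = 60)
  inp <- herd_model_inputs(herd)
  bad <- to_causal_structure(
    tibble::tibble(from = "a", to = "b"), trait_order = c("a", "b"))
  expect_error(run_sem(inp$at, inp$H_inv, bad, chain_config()),
               class = "lact_invalid_configuration")
})
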