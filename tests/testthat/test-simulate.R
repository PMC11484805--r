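test_that("ground-truth construction enforces its invariants", {
  truth <- default_ground_truth()
  L <- truth$lambda
  expect_true(all(L[upper.tri(L, diag = TRUE)] == 0))
  expect_equal(det(diag(6) - L), 1)
  expect_gt(min(eigen(truth$sigma_g, symmetric = TRUE)$values), 0)
  # reduced-form phenotypic variances are calibrated to 1
  Tm <- solve(diag(6) - L)
  S <- truth$sigma_g + truth$sigma_h + truth$sigma_e
  expect_equal(unname(diag(Tm %*% S %*% t(Tm))), rep(1, 6), tolerance = 1e-8)
  # heritabilities sit in the reported low-to-moderate band
  expect_true(all(truth$h2 >= 0.09 & truth$h2 <= 0.23))

  bad <- matrix(0.5, 6, 6) - diag(0.4, 6) # not PSD
  expect_error(
    ground_truth(truth$lambda, bad, truth$sigma_h, truth$sigma_e,
                 truth$dim_effects, truth$parity_effects),
    class = "lact_invalid_covariance")
  Lbad <- truth$lambda; Lbad[1, 6] <- 0.2
  expect_error(
    ground_truth(Lbad, truth$sigma_g, truth$sigma_h, truth$sigma_e,
                 truth$dim_effects, truth$parity_effects),
    class = "lact_invalid_input")
})

test_that("phenotype covariance follows the reduced-form identity", {
  truth <- default_ground_truth()
  n <- 20000
  ped <- simulate_pedigree(n, 0)
  # one herd-date per cow so the herd variance shows up cross-sectionally
  des <- tibble::tibble(animal = ped$animal, herd = 1L,
                        herd_date = seq_len(n), parity = 2L, dim = 100L)
  ph <- simulate_phenotypes(ped, des, truth, seed = 7)
  y <- attr(ph, "latent")
  Tm <- solve(diag(6) - truth$lambda)
  S_theory <- Tm %*% (truth$sigma_g + truth$sigma_h + truth$sigma_e) %*% t(Tm)
  expect_lt(max(abs(cov(y) - S_theory)), 0.03)
})

test_that("without recursion the covariance is just the component sum", {
  truth <- default_ground_truth()
  truth0 <- ground_truth(matrix(0, 6, 6), truth$sigma_g, truth$sigma_h,
                         truth$sigma_e, truth$dim_effects,
                         truth$parity_effects)
  n <- 15000
  ped <- simulate_pedigree(n, 0)
  des <- tibble::tibble(animal = ped$animal, herd = 1L,
                        herd_date = seq_len(n), parity = 2L, dim = 100L)
  ph <- simulate_phenotypes(ped, des, truth0, seed = 8)
  S <- truth$sigma_g + truth$sigma_h + truth$sigma_e
  expect_lt(max(abs(cov(attr(ph, "latent")) - S)), 0.03)
})

test_that("pedigree-driven genetic values reproduce A-structured covariance", {
  # across many independent families, cov(full sibs) = 0.5 Sigma_g
  truth <- default_ground_truth()
  set.seed(9)
  n_fam <- 4000
  founders <- tibble::tibble(animal = seq_len(2 * n_fam), sire = 0L, dam = 0L)
  offspring <- tibble::tibble(
    animal = 2 * n_fam + seq_len(2 * n_fam),
    sire = rep(seq(1, 2 * n_fam, by = 2), each = 2),
    dam = rep(seq(2, 2 * n_fam, by = 2), each = 2)
  )
  ped <- dplyr::bind_rows(founders, offspring)
  des <- tibble::tibble(animal = offspring$animal, herd = 1L,
                        herd_date = 1L, parity = 1L, dim = 50L)
  sib1 <- seq(1, 2 * n_fam, by = 2)
  # strip herd/residual: use a genetic-only truth
  t0 <- ground_truth(matrix(0, 6, 6), truth$sigma_g,
                     diag(1e-10, 6), diag(1e-10, 6),
                     truth$dim_effects * 0, truth$parity_effects * 0)
  ph <- simulate_phenotypes(ped, des, t0)
  y <- attr(ph, "latent")
  cross <- cov(y[sib1, ], y[sib1 + 1, ])
  expect_lt(max(abs(cross - 0.5 * truth$sigma_g)), 0.02)
})

test_that("simulated herds are reproducible and carry realistic scales", {
  h1 <- simulate_herd(n_cows = 120, n_snp = 100, n_genotyped = 30, seed = 3)
  h2 <- simulate_herd(n_cows = 120, n_snp = 100, n_genotyped = 30, seed = 3)
  expect_identical(h1$pedigree, h2$pedigree)
  expect_identical(h1$genotypes, h2$genotypes)
  expect_identical(h1$phenotypes, h2$phenotypes)

  # raw-scale means and SDs track the published population statistics
  big <- simulate_herd(n_cows = 1250, n_snp = 10, n_genotyped = 5, seed = 4)
  st <- reference_trait_stats()
  for (tr in c("dMEO", "glucose", "CHOL", "BHB", "urea", "milk_yield")) {
    i <- match(tr, st$trait)
    expect_lt(abs(mean(big$phenotypes[[tr]]) - st$mean[i]), 0.10 * st$mean[i])
    expect_lt(abs(sd(big$phenotypes[[tr]]) - st$sd[i]), 0.15 * st$sd[i])
  }
  # herd-date structure: 5 herds x 4 dates
  expect_lte(dplyr::n_distinct(big$design$herd_date), 20)
  expect_equal(sort(unique(big$design$herd)), 1:5)
  expect_true(all(big$design$dim >= 5 & big$design$dim <= 598))
})
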