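test_that("pedigree simulation honours founder and generation structure", {
  p0 <- simulate_pedigree(10, 0)
  expect_equal(nrow(p0), 10)
  expect_true(all(p0$sire == 0) && all(p0$dam == 0))

  # two founders, one generation, three offspring: forced parentage
  p1 <- simulate_pedigree(2, 1, offspring_per_mating = 3, seed = 1)
  expect_equal(nrow(p1), 5)
  off <- p1[p1$generation == 1, ]
  expect_equal(nrow(off), 3)
  expect_true(all(off$sire == 2) && all(off$dam == 1))

  expect_error(simulate_pedigree(1, 2), class = "lact_invalid_configuration")
})

test_that("pedigree simulation is reproducible bit-exactly by seed", {
  a <- simulate_pedigree(50, 3, 2, seed = 1)
  b <- simulate_pedigree(50, 3, 2, seed = 1)
  expect_identical(a, b)
  validate_pedigree(a)
  # parents precede offspring
  pos <- match(a$animal, a$animal)
  expect_true(all(a$sire == 0 | match(a$sire, a$animal) < pos))
})

test_that("ancestral-closure pruning keeps ancestry and relabels the cut", {
  ped <- random_pedigree(60, seed = 5)
  cows <- ped$animal[ped$generation == max(ped$generation)][1:10]
  pr <- prune_pedigree(ped, cows, generations = 2)
  expect_true(all(cows %in% pr$animal))
  validate_pedigree(pr)
  # every kept parent link refers to a kept animal
  expect_true(all(pr$sire %in% c(0L, pr$animal)))
  # unlimited depth keeps at least as many ancestors
  pr_all <- prune_pedigree(ped, cows, generations = Inf)
  expect_gte(nrow(pr_all), nrow(pr))
})

test_that("inbreeding coefficients match the tabular A diagonal", {
  # offspring of paternal half sibs has F = 0.125
  ped <- toy_pedigree()
  f <- inbreeding(ped)
  expect_equal(unname(f[7]), 0.125)
  expect_equal(unname(f[1:6]), rep(0, 6))
  for (seed in 1:3) {
    rp <- random_pedigree(40, seed = seed)
    expect_equal(unname(inbreeding(rp)), unname(diag(build_A(rp)) - 1),
                 tolerance = 1e-12)
  }
})

test_that("gene dropping respects Mendelian transmission and frequencies", {
  # founder-only panel at fixed frequency 0.5: mean dosage ~ 1 within 3 SE
  ped <- simulate_pedigree(40, 0)
  g <- simulate_genotypes(ped, 10000, maf_range = 0.5, seed = 1)
  se <- sqrt(0.5 / (40 * 10000)) # var(dosage)=2pq=0.5
  expect_equal(mean(g), 1, tolerance = 3 * se)
  expect_true(all(g %in% 0:2))

  # offspring of two dosage-0 parents is dosage 0
  trio <- tibble::tibble(animal = 1:3, sire = c(0L, 0L, 2L), dam = c(0L, 0L, 1L))
  gt <- simulate_genotypes(trio, 500, maf_range = c(0.2, 0.5), seed = 2)
  zero <- gt[1, ] == 0 & gt[2, ] == 0
  expect_true(all(gt[3, zero] == 0))

  # parent-offspring dosage correlation approximates kinship 0.5
  ped2 <- simulate_pedigree(200, 1, offspring_per_mating = 1, seed = 3,
                            n_sires = 100)
  g2 <- simulate_genotypes(ped2, 800, seed = 4)
  off <- ped2[ped2$generation == 1, ]
  p <- attr(g2, "allele_freq")
  ctr <- sweep(g2, 2, 2 * p)
  cors <- mapply(function(o, s) {
    stats::cor(ctr[as.character(o), ], ctr[as.character(s), ])
  }, off$animal, off$sire)
  expect_equal(mean(cors), 0.5, tolerance = 0.05)

  expect_error(simulate_genotypes(trio[0, ], 10), class = "lact_invalid_input")
  expect_error(simulate_genotypes(trio, 10, maf_range = c(0, 0.6)),
               class = "lact_invalid_input")
})

test_that("missing-dosage injection hits the requested rate", {
  ped <- simulate_pedigree(50, 0)
  g <- simulate_genotypes(ped, 400, seed = 9, missing_rate = 0.1)
  expect_equal(mean(is.na(g)), 0.1, tolerance = 0.05)
})
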