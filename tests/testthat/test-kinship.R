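test_that("A has textbook values on simple pedigrees", {
  founders <- simulate_pedigree(5, 0)
  expect_equal(unname(build_A(founders)), diag(5), ignore_attr = TRUE)

  trio <- tibble::tibble(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  A <- build_A(trio)
  expect_equal(A["3", "1"], 0.5)
  expect_equal(A["3", "3"], 1.0)
  # half-sib-mating offspring carries inbreeding on the diagonal
  A7 <- build_A(toy_pedigree())
  expect_equal(A7["7", "7"], 1.125)
})

test_that("Henderson's rules reproduce the dense inverse of tabular A", {
  for (seed in 1:5) {
    ped <- random_pedigree(25, seed = seed)
    ped <- ped[seq_len(min(nrow(ped), 25)), ]
    ped$sire[!(ped$sire %in% ped$animal)] <- 0L
    ped$dam[!(ped$dam %in% ped$animal)] <- 0L
    A <- build_A(ped)
    Ainv <- as.matrix(build_A_inverse(ped))
    expect_lt(max(abs(Ainv - solve(A))), 1e-8)
  }
})

test_that("A entries are bounded and inbreeding is non-negative", {
  ped <- random_pedigree(120, seed = 9)
  A <- build_A(ped)
  expect_true(all(A >= 0 - 1e-12 & A <= 2 + 1e-12))
  expect_true(all(diag(A) >= 1 - 1e-12))
})

test_that("A22 equals A restricted to the genotyped animals", {
  ped <- random_pedigree(60, seed = 3)
  ids <- sample(ped$animal, 12)
  A22 <- build_A22(ped, ids)
  A <- build_A(ped)
  expect_equal(A22, A[as.character(ids), as.character(ids)],
               ignore_attr = TRUE)
  # and equals A built on the ancestral closure, restricted
  pr <- prune_pedigree(ped, ids, generations = Inf)
  expect_equal(unname(build_A(pr)[as.character(ids), as.character(ids)]),
               unname(A22), ignore_attr = TRUE)
  expect_error(build_A22(ped, c(ids, 99999L)), class = "lact_id_mismatch")
})

test_that("G matches brute-force centered cross products on a toy panel", {
  set.seed(5)
  M <- matrix(rbinom(5 * 8, 2, 0.4), 5, 8,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:8)))
  G <- build_G(M)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(G[i, j], sum((M[i, ] - 2 * p) * (M[j, ] - 2 * p)) / denom)
  }
  # identical genotypes give identical rows/diagonal entries
  M2 <- rbind(M, a6 = M[1, ])
  G2 <- build_G(M2)
  expect_equal(G2["a6", "a6"], G2["a1", "a1"])
  expect_equal(G2["a6", "a1"], G2["a1", "a1"])
  expect_error(build_G(matrix(2, 3, 4)), class = "lact_zero_denominator")
  expect_error(build_G(matrix(c(NA, 1, 1, 0), 2, 2)),
               class = "lact_invalid_input")
})

test_that("G diagonal averages 1 in an HWE founder population", {
  ped <- simulate_pedigree(300, 0)
  g <- simulate_genotypes(ped, 3000, seed = 6)
  G <- build_G(g)
  expect_equal(mean(diag(G)), 1, tolerance = 0.03)
})

test_that("blended G is positive definite", {
  ped <- random_pedigree(80, seed = 7)
  ids <- ped$animal[ped$generation == max(ped$generation)][1:20]
  g <- simulate_genotypes(ped, 10, seed = 8)[as.character(ids), ]
  G <- build_G(g) # 10 markers, 20 animals: singular before blending
  A22 <- build_A22(ped, ids)
  Gb <- blend_G(G, A22)
  expect_gt(min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("H-inverse reduces to A-inverse without genomic information", {
  ped <- random_pedigree(40, seed = 2)
  Ainv <- build_A_inverse(ped)
  H0 <- single_step_H_inverse(ped, NULL)
  expect_equal(as.matrix(H0), as.matrix(Ainv), ignore_attr = TRUE)
  # G = A22 makes the correction cancel exactly
  ids <- sample(ped$animal, 8)
  A22 <- build_A22(ped, ids)
  H1 <- build_H_inverse(Ainv, solve(A22), solve(A22), ids)
  expect_equal(as.matrix(H1), as.matrix(Ainv), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("H-inverse equals the dense block formula", {
  ped <- random_pedigree(36, seed = 4)
  ped <- ped[1:12, ]
  ped$sire[!(ped$sire %in% ped$animal)] <- 0L
  ped$dam[!(ped$dam %in% ped$animal)] <- 0L
  ids <- as.character(ped$animal[8:12])
  g <- simulate_genotypes(ped, 60, seed = 5)[ids, ]
  A <- build_A(ped)
  A22 <- A[ids, ids]
  Gb <- blend_G(build_G(g), A22)
  H <- single_step_H_inverse(ped, g)
  dense <- solve(A)
  idx <- match(ids, rownames(A))
  dense[idx, idx] <- dense[idx, idx] + solve(Gb) - solve(A22)
  expect_equal(as.matrix(H), dense, ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(build_H_inverse(build_A_inverse(ped), solve(A22), solve(Gb),
                               c("nope", ids[-1])),
               class = "lact_id_mismatch")
})
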