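test_that("BIC score matches an independent regression-based evaluation", {
  set.seed(1)
  m <- simulate_network_residuals(
    tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                   lambda = c(0.6, 0.5)),
    n = 400, nodes = c("a", "b", "c", "d"))
  for (amat in all_dags(colnames(m))[c(1, 5, 40, 100, 300)]) {
    dag <- structure(list(nodes = colnames(m), amat = amat),
                     class = "lact_dag")
    expect_equal(bic_score(m, dag), bic_oracle(m, amat), tolerance = 1e-8)
  }
  # permutation of rows leaves the score unchanged
  dag <- new_dag(colnames(m), tibble::tibble(from = "a", to = "b"))
  expect_equal(bic_score(m, dag), bic_score(m[sample(nrow(m)), ], dag))
})

test_that("penalty beats spurious fit for independent columns", {
  set.seed(2)
  m <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("x", "y")))
  expect_gt(bic_score(m, new_dag(c("x", "y"))),
            bic_score(m, new_dag(c("x", "y"),
                                 tibble::tibble(from = "x", to = "y"))))
  expect_equal(sum(hill_climb(m)$amat), 0)
})

test_that("hill climbing attains the exhaustive optimum on 4-node data", {
  dags <- all_dags(c("a", "b", "c", "d"))
  expect_length(dags, 543) # all labeled DAGs on 4 nodes
  for (seed in 1:4) {
    paths <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "d"),
                            lambda = c(0.5, -0.4, 0.6))
    m <- simulate_network_residuals(paths, n = 1000,
                                    nodes = c("a", "b", "c", "d"), seed = seed)
    hc <- hill_climb(m)
    best <- max(vapply(dags, function(am) {
      bic_oracle(m, am)
    }, numeric(1)))
    expect_equal(attr(hc, "score"), best, tolerance = 1e-6)
    # score trajectory increases strictly and ends above the empty graph
    traj <- attr(hc, "trajectory")
    expect_true(all(diff(traj) > 0))
    expect_gte(attr(hc, "score"), bic_score(m, new_dag(colnames(m))))
  }
})

test_that("a simulated chain yields exactly its skeleton", {
  m <- simulate_network_residuals(
    tibble::tibble(from = c("x", "y"), to = c("y", "z"), lambda = c(0.7, 0.7)),
    n = 5000, nodes = c("x", "y", "z"), seed = 3)
  dag <- hill_climb(m)
  skel <- dag$amat | t(dag$amat)
  expect_true(skel["x", "y"] && skel["y", "z"] && !skel["x", "z"])
})

test_that("bootstrap tallies strengths and directions coherently", {
  set.seed(4)
  x <- rnorm(1000); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(1000)
  m <- cbind(u = x, v = y)
  # single replicate: strengths are 0/1 and match that replicate's DAG
  net1 <- bootstrap_network(m, n_boot = 1, seed = 5)
  expect_true(all(net1$edges$strength %in% c(0, 1)))
  # strong dependence is found in essentially every resample
  net <- bootstrap_network(m, n_boot = 200, seed = 6)
  e <- net$edges
  expect_equal(e$strength[1], 1, tolerance = 0.01)
  # the two orientations of a pair share strength and split direction
  expect_equal(e$strength[e$from == "u"], e$strength[e$from == "v"])
  expect_equal(sum(e$direction), 1)
  # fixed seed reproduces tallies exactly
  net_b <- bootstrap_network(m, n_boot = 200, seed = 6)
  expect_identical(net$edges, net_b$edges)
})

test_that("causal structure lays retained edges into lower-triangular form", {
  empty <- new_dag(lact_traits())
  cs0 <- to_causal_structure(empty)
  expect_true(all(!cs0$pattern))

  cs <- to_causal_structure(default_path_table())
  # published layout: trait order preserved, 8 free entries
  expect_identical(cs$order, lact_traits())
  expect_equal(sum(cs$pattern), 8)
  expect_true(all(!cs$pattern[upper.tri(cs$pattern, diag = TRUE)]))
  expect_true(cs$pattern["CHOL", "dMEO"])
  expect_true(cs$pattern["urea", "BHB"])
  # (I - Lambda) for any pattern is unit-determinant triangular
  expect_equal(det(diag(6) - cs$pattern * 0.3), 1)

  expect_error(
    to_causal_structure(tibble::tibble(from = c("a", "b"), to = c("b", "a")),
                        trait_order = c("a", "b")),
    class = "lact_cycle_error")
})

test_that("network recovery finds strong paths at study scale", {
  # strong published paths reach high bootstrap support at n = 1254
  m <- simulate_network_residuals(default_path_table(), 1254, seed = 8)
  net <- bootstrap_network(m, n_boot = 120, seed = 9)
  e <- tidy(net)
  strong <- c("glucose->BHB", "dMEO->CHOL", "glucose->urea", "CHOL->urea")
  key <- paste0(e$from, "->", e$to)
  for (s in strong) {
    expect_gte(e$strength[key == s], 0.9)
  }
})
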