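test_that("random graphs respect density limits and binomial moments", {
  expect_equal(sum(random_graph(5, 0, seed = 1)), 0)
  expect_equal(sum(random_graph(5, 1, seed = 1)) / 2, 10)
  expect_error(random_graph(5, 1.2, seed = 1), "density")

  counts <- vapply(1:300, function(s)
    sum(random_graph(20, 0.3, seed = s)) / 2, numeric(1))
  se <- sqrt(190 * 0.3 * 0.7) / sqrt(300)
  expect_lt(abs(mean(counts) - 0.3 * 190), 3 * se)
})

test_that("ground-truth bundles honor the graph and the effect-size floor", {
  gt0 <- sample_ground_truth(empty_graph(4), seed = 1)
  expect_true(all(gt0$K[upper.tri(gt0$K)] == 0))
  expect_equal(gt0$R, diag(4), ignore_attr = TRUE)
  expect_equal(sum(gt0$truth$T_mask), 0)

  G <- random_graph(8, 0.3, seed = 2)
  gt <- sample_ground_truth(G, seed = 3, min_abs_partial = 0.25)
  edges <- G == 1 & upper.tri(G)
  expect_true(all(abs(gt$R[edges]) >= 0.25))
  expect_true(all(gt$K[G == 0 & upper.tri(G)] == 0))
  expect_true(all(eigen(gt$K, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_identical(gt$truth$T_mask, G, ignore_attr = TRUE)

  # an unreachable floor errors with advice
  expect_error(sample_ground_truth(G, seed = 4, min_abs_partial = 0.95,
                                   max_retries = 20), "lower the threshold")
})

test_that("time-series generator is deterministic and consistent", {
  K <- rand_pd(3, 5)
  X1 <- simulate_timeseries(K, 50, seed = 6)
  X2 <- simulate_timeseries(K, 50, seed = 6)
  expect_identical(unclass(X1), unclass(X2))
  expect_error(simulate_timeseries(K, 0, seed = 1), "at least 1")

  # empirical covariance approaches K^{-1}
  Sig <- solve(K)
  Xbig <- simulate_timeseries(K, 1e5, seed = 7)
  emp <- crossprod(unclass(Xbig)) / 1e5
  expect_lt(max(abs(emp - Sig)), 4 * max(diag(Sig)) / sqrt(1e5) * 3)
  Xsmall <- simulate_timeseries(K, 1000, seed = 7)
  emp_small <- crossprod(unclass(Xsmall)) / 1000
  expect_gt(norm(emp_small - Sig, "F") / norm(emp - Sig, "F"), 1)
})

test_that("streamline generator closes rows and separates edge counts", {
  G <- random_graph(5, 0.4, seed = 8)
  S <- simulate_streamlines(G, row_totals = 700, seed = 9)
  expect_equal(unname(rowSums(S)), rep(700, 5))
  expect_equal(unname(rowSums(simulate_streamlines(G, row_totals = 0, seed = 9))),
               rep(0, 5))
  expect_error(simulate_streamlines(G, alpha = -1, row_totals = 10, seed = 1),
               "positive")

  # alpha > beta puts more mass on edges (averaged over replicates)
  G1 <- graph_from_bits(c(1L, 0L, 0L), 3)  # row 1: edge to 2, non-edge to 3
  on_edge <- off_edge <- numeric(400)
  for (r in 1:400) {
    S <- simulate_streamlines(G1, alpha = 1, beta = 0.5, row_totals = 200,
                              seed = 100 + r)
    on_edge[r] <- S[1, 2]; off_edge[r] <- S[1, 3]
  }
  se <- sd(on_edge - off_edge) / sqrt(400)
  expect_gt(mean(on_edge) - mean(off_edge), 3 * se)

  # ideal streamlines: noise-free, concentrated on edges
  Si <- ideal_streamlines(G, row_totals = 1000)
  expect_true(all(Si[G == 0] == 0))
  deg <- unname(rowSums(G))
  expect_equal(unname(rowSums(Si)), ifelse(deg > 0, 1000, 0))
})

test_that("scenario wrapper ties the pieces together reproducibly", {
  sc <- simulate_scenario(p = 5, n = 100, density = 0.4, row_totals = 300,
                          seed = 10)
  expect_equal(dim(sc$X), c(100, 5))
  expect_equal(unname(rowSums(sc$S)), rep(300, 5))
  expect_identical(sc$truth$T_mask, sc$graph, ignore_attr = TRUE)
  sc2 <- simulate_scenario(p = 5, n = 100, density = 0.4, row_totals = 300,
                           seed = 10)
  expect_identical(unclass(sc$X), unclass(sc2$X))
})
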