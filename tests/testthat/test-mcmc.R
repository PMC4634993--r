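test_that("configuration validates sizes and demands a seed", {
  expect_error(mcmc_config(seed = NULL), "seed")
  expect_error(mcmc_config(1000, thin_to = 900, seed = 1), "post-burn-in")
  cfg <- mcmc_config(1000, thin_to = 100, seed = 1)
  expect_equal(cfg$burn_in, 200L)
  idx <- bggm:::thin_indices(cfg)
  expect_equal(length(idx), 100L)
  expect_true(all(diff(idx) > 0) && max(idx) <= 1000 && min(idx) > 200)
})

test_that("hard prior constraints hold exactly in every draw", {
  set.seed(8)
  X <- matrix(rnorm(3 * 60), 60, 3)
  cfg <- mcmc_config(2000, thin_to = 200, n_chains = 1, seed = 3)

  ps0 <- sample_joint_posterior(X, theta = 0, cfg)
  expect_true(all(ps0$graphs == 0L))
  expect_true(all(apply(ps0$precisions, 3, function(K)
    all(K[upper.tri(K)] == 0))))

  th <- matrix(0.5, 3, 3)
  th[1, 2] <- th[2, 1] <- 1; th[1, 3] <- th[3, 1] <- 0
  ps1 <- sample_joint_posterior(X, edge_prior(th), cfg)
  expect_true(all(ps1$graphs[1, 2, ] == 1L))
  expect_true(all(ps1$graphs[1, 3, ] == 0L))
  expect_true(all(ps1$precisions[1, 3, ] == 0))
})

test_that("every retained precision is PD and respects its graph", {
  set.seed(9)
  X <- matrix(rnorm(4 * 80), 80, 4)
  cfg <- mcmc_config(3000, thin_to = 150, n_chains = 1, seed = 4)
  ps <- sample_joint_posterior(X, 0.5, cfg)
  for (s in seq_len(dim(ps$graphs)[3])) {
    K <- ps$precisions[, , s]
    G <- ps$graphs[, , s]
    expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > 0))
    expect_true(all(K[G == 0 & upper.tri(G)] == 0))
    expect_true(all(K[G == 1 & upper.tri(G)] != 0))
  }
})

test_that("with no data the chain reproduces the edge prior", {
  # flat data: Sigma = 0, n = 0 targets the prior itself
  th <- matrix(0, 3, 3)
  th[1, 2] <- 0.3; th[1, 3] <- 0.5; th[2, 3] <- 0.8
  th <- edge_prior(th + t(th))
  cfg <- mcmc_config(20000, thin_to = 2000, n_chains = 1, seed = 11)
  ps <- bggm:::sample_posterior_scatter(matrix(0, 3, 3), 0, th, 3, diag(3), cfg)
  freq <- apply(ps$graphs, c(1, 2), mean)
  expect_lt(abs(freq[1, 2] - 0.3), 0.05)
  expect_lt(abs(freq[1, 3] - 0.5), 0.05)
  expect_lt(abs(freq[2, 3] - 0.8), 0.05)
})

test_that("posterior edge probabilities track the exact enumeration oracle", {
  sc <- simulate_scenario(p = 3, n = 200, density = 0.5, seed = 31)
  ex <- exact_small_p_posterior(sc$X, theta = 0.5)
  cfg <- mcmc_config(8000, thin_to = 500, n_chains = 2, seed = 32)
  ps <- sample_joint_posterior(sc$X, 0.5, cfg)
  sm <- posterior_summaries(ps)
  expect_lt(max(abs(sm$edge_probabilities - ex$edge_probabilities)), 0.05)
})

test_that("runs are reproducible and alpha = beta reduces fusion to fMRI-only", {
  sc <- simulate_scenario(p = 4, n = 100, density = 0.4, row_totals = 500,
                          seed = 41)
  cfg <- mcmc_config(2000, thin_to = 100, n_chains = 2, seed = 42)
  a <- sample_joint_posterior(sc$X, 0.5, cfg)
  b <- sample_joint_posterior(sc$X, 0.5, cfg)
  expect_identical(a$graphs, b$graphs)
  expect_identical(a$precisions, b$precisions)

  f <- sample_fused_posterior(sc$X, sc$S, 0.5, cfg, alpha = 0.7, beta = 0.7)
  expect_identical(f$graphs, a$graphs)

  expect_error(sample_fused_posterior(sc$X, sc$S[c(2, 1, 3, 4), c(2, 1, 3, 4)],
                                      0.5, cfg), "labels")
})

test_that("convergence report flags disagreeing chains", {
  Gfull <- full_graph(3); Gempty <- empty_graph(3)
  same <- manual_samples(rep(list(Gfull), 20), chain = rep(1:2, each = 10))
  rep_same <- convergence_report(same)
  expect_equal(rep_same$max_discrepancy, 0)
  expect_true(rep_same$passed)

  locked <- manual_samples(c(rep(list(Gempty), 10), rep(list(Gfull), 10)),
                           chain = rep(1:2, each = 10))
  rep_locked <- convergence_report(locked)
  expect_equal(rep_locked$max_discrepancy, 1)
  expect_false(rep_locked$passed)

  expect_error(convergence_report(manual_samples(list(Gfull))), "two chains")
})
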