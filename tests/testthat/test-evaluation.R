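test_that("reconstruction errors match the hand-computed fixture", {
  Rstar <- diag(3); Rstar[1, 2] <- Rstar[2, 1] <- 0.5
  mask <- matrix(0L, 3, 3); mask[1, 2] <- mask[2, 1] <- 1L
  truth <- ground_truth(Rstar, mask)

  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.3
  R[1, 3] <- R[3, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- 0.1
  err <- reconstruction_errors(truth, R)
  expect_equal(err$eta, (0.2 + 0.1 + 0.1) / 3, tolerance = 1e-12)
  expect_equal(err$eta_tp, 0.2, tolerance = 1e-12)
  expect_equal(err$eta_tn, 0.1, tolerance = 1e-12)

  perfect <- reconstruction_errors(truth, Rstar)
  expect_equal(unlist(perfect), c(eta = 0, eta_tp = 0, eta_tn = 0))

  # all-edge mask: eta_tn undefined, signaled
  full_truth <- ground_truth(Rstar, full_graph(3))
  expect_warning(err2 <- reconstruction_errors(full_truth, R), "undefined")
  expect_true(is.na(err2$eta_tn))

  # decomposition identity eta * npairs = eta_tp * N_tp + eta_tn * N_tn
  set.seed(2)
  for (rep in 1:5) {
    G <- random_graph(4, 0.5, seed = rep)
    if (sum(G) %in% c(0, 12)) next
    Rs <- diag(4); Rs[G == 1] <- 0.4
    tr <- ground_truth(Rs, G)
    Re <- precision_to_partial(rand_pd(4, rep + 10))
    e <- reconstruction_errors(tr, Re)
    ntp <- sum(G[upper.tri(G)]); ntn <- 6 - ntp
    expect_equal(e$eta * 6, e$eta_tp * ntp + e$eta_tn * ntn, tolerance = 1e-12)
  }
})

test_that("z-scores standardize against the posterior error cloud", {
  expect_equal(z_score(2, c(1, 2, 3)), 0)
  expect_equal(z_score(3, c(1.5, 2.5)), (3 - 2) / sd(c(1.5, 2.5)))
  set.seed(3)
  s <- rnorm(50, 2, 1)
  expect_equal(z_score(3, s), (3 - mean(s)) / sd(s), tolerance = 1e-12)
  expect_error(z_score(1, c(2, 2)), "spread")
  expect_error(z_score(1, 2), "two")
})

test_that("plug-in entropy and MAP probability count graph frequencies", {
  g1 <- empty_graph(3); g2 <- full_graph(3)
  expect_equal(posterior_entropy(manual_samples(rep(list(g1), 10))), 0)

  eight <- lapply(0:7, function(b) graph_from_bits(as.integer(intToBits(b))[1:3], 3))
  expect_equal(posterior_entropy(manual_samples(eight)), 3)

  mix <- manual_samples(c(rep(list(g1), 3), list(g2)))
  expect_equal(posterior_entropy(mix), 0.811278124459133, tolerance = 1e-12)

  expect_equal(map_probability(manual_samples(rep(list(g2), 5)))$probability, 1)
  four <- map_probability(manual_samples(eight[1:4]))
  expect_equal(four$probability, 0.25)
  expect_length(four$ties, 4)
  expect_equal(four$graph, eight[[1]], ignore_attr = TRUE)

  mode6 <- manual_samples(c(rep(list(eight[[2]]), 6), rep(list(eight[[3]]), 3),
                            rep(list(eight[[4]]), 1)))
  m <- map_probability(mode6)
  expect_equal(m$probability, 0.6)
  expect_equal(m$graph, eight[[2]], ignore_attr = TRUE)
})

test_that("posterior summaries aggregate draws correctly", {
  g1 <- empty_graph(2); g2 <- full_graph(2)
  k1 <- diag(2); k2 <- matrix(c(2, 1, 1, 2), 2)

  single <- posterior_summaries(manual_samples(list(g2), list(k2)))
  expect_true(all(single$edge_probabilities %in% c(0, 1)))
  expect_equal(single$partial_variance, matrix(0, 2, 2), ignore_attr = TRUE)

  both <- posterior_summaries(manual_samples(list(g1, g2), list(k1, k2)))
  expect_equal(both$edge_probabilities[1, 2], 0.5)
  expect_equal(both$density, 0.5)
  # mean partial correlation of r = 0 and r = -0.5
  expect_equal(both$partial_mean[1, 2], -0.25)
  expect_equal(both$partial_variance[1, 2], 0.0625, tolerance = 1e-12)

  # four hand-built draws
  ks <- list(diag(3), rand_pd(3, 1), rand_pd(3, 2), rand_pd(3, 3))
  gs <- lapply(ks, function(K) {
    G <- 1L * (abs(K) > 1e-12); diag(G) <- 0L; G
  })
  sm <- posterior_summaries(manual_samples(gs, ks))
  rs <- sapply(ks, function(K) precision_to_partial(K)[1, 2])
  expect_equal(sm$partial_mean[1, 2], mean(rs), tolerance = 1e-12)
  expect_equal(sm$partial_variance[1, 2], mean(rs^2) - mean(rs)^2,
               tolerance = 1e-12)
})

test_that("edge ranking AUC agrees with an independent ROC implementation", {
  set.seed(4)
  G <- random_graph(6, 0.4, seed = 5)
  scores <- matrix(runif(36), 6); scores <- (scores + t(scores)) / 2
  mine <- edge_roc_auc(G, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = G[upper.tri(G)], predictor = scores[upper.tri(scores)],
    quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("enumeration oracle agrees with quadrature on p = 2", {
  set.seed(6)
  X <- standardize_timeseries(matrix(rnorm(60), 30, 2))
  ex <- exact_small_p_posterior(X, theta = 0.5)

  # quadrature over the precision entries for the marginal likelihood of the
  # full and the empty graph; kernel |K|^{(d-2)/2} exp(-<K, D>/2)
  sc <- scatter_matrix(X)
  Dstar <- diag(2) + sc$sigma
  quad_z_full <- function(delta, D, gmax, omax, npts = 400) {
    g <- seq(gmax / npts * 0.5, gmax, length.out = npts)
    goff <- seq(-omax, omax, length.out = npts)
    dg <- g[2] - g[1]; dgo <- goff[2] - goff[1]
    tot <- 0
    for (k11 in g) {
      dt <- outer(g * k11, goff^2, "-")
      ek <- exp(-0.5 * (k11 * D[1, 1] + outer(g * D[2, 2], 2 * goff * D[1, 2], "+")))
      v <- ifelse(dt > 0, dt^((delta - 2) / 2) * ek, 0)
      tot <- tot + sum(v) * dg * dg * dgo
    }
    tot
  }
  quad_z_empty <- function(delta, D, gmax) {
    g <- seq(1e-6, gmax, length.out = 40000)
    dg <- g[2] - g[1]
    prod(vapply(1:2, function(i)
      sum(g^((delta - 2) / 2) * exp(-0.5 * g * D[i, i])) * dg, numeric(1)))
  }
  n <- sc$n
  # prior integrals are heavy-tailed (delta = 3): wide ranges; posterior
  # integrals concentrate near (delta + n) * Dstar^{-1}: fine ranges
  lm_full <- -n * log(2 * pi) + log(quad_z_full(3 + n, Dstar, 8, 4)) -
    log(quad_z_full(3, diag(2), 60, 25, 600))
  lm_empty <- -n * log(2 * pi) + log(quad_z_empty(3 + n, Dstar, 8)) -
    log(quad_z_empty(3, diag(2), 60))
  post_edge <- 1 / (1 + exp(lm_empty - lm_full))  # theta = 0.5 cancels
  expect_equal(ex$edge_probabilities[1, 2], post_edge, tolerance = 1e-3)
  expect_equal(sum(exp(ex$log_posterior)), 1, tolerance = 1e-10)
})

test_that("exact posterior is equivariant under region permutation", {
  sc <- simulate_scenario(p = 3, n = 150, density = 0.5, seed = 7)
  ex <- exact_small_p_posterior(sc$X, theta = 0.5)
  perm <- c(3, 1, 2)
  Xp <- timeseries_data(unclass(sc$X)[, perm])
  exp_perm <- exact_small_p_posterior(Xp, theta = 0.5)
  expect_equal(exp_perm$edge_probabilities,
               ex$edge_probabilities[perm, perm], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(exact_small_p_posterior(matrix(rnorm(50), 10, 5)), "p <= 4")
})
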