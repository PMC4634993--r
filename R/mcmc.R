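# Joint MCMC over (G, K): chain management, thinning, and convergence
# diagnostics.  The compiled kernel performs, per iteration, an exact
# conjugate G-Wishart refresh of K given G followed by a single-edge
# exchange move in which an auxiliary precision matrix drawn from the prior
# under the proposed graph cancels the intractable normalizing constants.

#' MCMC configuration
#'
#' @param n_iterations Total iterations per chain (default 50000).
#' @param burn_in Iterations discarded from the front of each chain; defaults
#'   to 20\% of `n_iterations`.
#' @param thin_to Number of retained draws per chain after uniform thinning
#'   of the post-burn-in iterations (default 1000).
#' @param n_chains Number of independent chains (default 2).
#' @param seed Integer seed; mandatory, all chains derive from it.
#' @return An object of class `bggm_mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 50000L, burn_in = NULL,
                        thin_to = 1000L, n_chains = 2L, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("`seed` is mandatory in the MCMC config", call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in %||% floor(0.2 * n_iterations))
  thin_to <- as.integer(thin_to)
  n_chains <- as.integer(n_chains)
  if (n_iterations < 1L || thin_to < 1L || n_chains < 1L || burn_in < 0L)
    stop("MCMC sizes must be positive (burn-in nonnegative)", call. = FALSE)
  if (thin_to > n_iterations - burn_in)
    stop(sprintf("`thin_to` (%d) exceeds the %d post-burn-in iterations",
                 thin_to, n_iterations - burn_in), call. = FALSE)
  structure(list(n_iterations = n_iterations, burn_in = burn_in,
                 thin_to = thin_to, n_chains = n_chains,
                 seed = as.integer(seed)),
            class = "bggm_mcmc_config")
}

# uniform thinning: strictly increasing retained iteration indices
thin_indices <- function(cfg) {
  span <- cfg$n_iterations - cfg$burn_in
  cfg$burn_in + ceiling(seq_len(cfg$thin_to) * (span / cfg$thin_to))
}

# Workhorse shared by the plain and fused samplers; operates on the scatter
# statistics so tests can target the prior directly with Sigma = 0, n = 0.
sample_posterior_scatter <- function(Sigma, n, theta, delta, D, cfg,
                                     S = NULL, alpha = 1, beta = 0.5,
                                     labels = NULL, tol = 1e-8, maxit = 1000L) {
  p <- ncol(Sigma)
  theta <- as_edge_prior(theta, p, labels)
  if (is.null(D)) D <- diag(p)
  check_pd(D, "D")
  fused <- !is.null(S)
  Sm <- if (fused) matrix(as.integer(S), p, p) else matrix(0L, p, p)
  adj0 <- matrix(0L, p, p)
  adj0[theta == 1] <- 1L  # hard-present edges are in every graph
  keep <- integer(cfg$n_iterations)
  keep[thin_indices(cfg)] <- 1L

  res <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_chains), function(ch) {
      .bggm_chain_cpp(Sigma, n, delta, D, unclass(theta), fused, Sm,
                      alpha, beta, cfg$n_iterations, keep, adj0, tol,
                      as.integer(maxit))
    })
  })

  Tc <- cfg$thin_to
  graphs <- array(0L, dim = c(p, p, Tc * cfg$n_chains))
  precisions <- array(0, dim = c(p, p, Tc * cfg$n_chains))
  for (ch in seq_len(cfg$n_chains)) {
    sl <- (ch - 1L) * Tc + seq_len(Tc)
    graphs[, , sl] <- res[[ch]]$G
    precisions[, , sl] <- res[[ch]]$K
  }
  labels <- labels %||% colnames(Sigma) %||% paste0("V", seq_len(p))
  structure(list(
    graphs = graphs, precisions = precisions,
    chain = rep(seq_len(cfg$n_chains), each = Tc),
    region_labels = labels,
    meta = list(seed = cfg$seed, n_iterations = cfg$n_iterations,
                burn_in = cfg$burn_in, thin_to = cfg$thin_to,
                n_chains = cfg$n_chains, fused = fused,
                delta = delta, alpha = if (fused) alpha else NA_real_,
                beta = if (fused) beta else NA_real_,
                acceptance_rates = vapply(res, `[[`, numeric(1),
                                          "acceptance_rate"))),
    class = "bggm_samples")
}

#' Sample the joint posterior over graph and precision matrix
#'
#' Approximates \eqn{P(G, K \mid X) \propto P(X\mid K) P(K\mid G) P(G)} by
#' MCMC: each iteration refreshes \eqn{K} exactly from its conjugate
#' G-Wishart conditional and then proposes flipping one uniformly chosen
#' free edge, accepted through an exchange step whose auxiliary prior draw
#' cancels the graph normalizing constants.  Pairs with hard prior
#' probability 0 or 1 are never proposed, so such constraints hold exactly
#' in every retained draw.
#'
#' @param X A [timeseries_data()] object or numeric matrix (rows = time
#'   points, columns = regions).
#' @param theta Edge prior: scalar, matrix, or [edge_prior()] (default 0.5,
#'   no preference for dependence or independence).
#' @param cfg An [mcmc_config()].
#' @param delta,D G-Wishart prior degrees of freedom and scale (defaults 3
#'   and identity, a vague prior on the precision).
#' @param standardize If `TRUE`, columns of `X` are standardized to zero
#'   mean, unit variance before inference.
#' @return A `bggm_samples` object holding paired graph/precision draws from
#'   all chains, with provenance in `$meta`.
#' @seealso [sample_fused_posterior()], [posterior_summaries()],
#'   [convergence_report()]
#' @export
sample_joint_posterior <- function(X, theta = 0.5, cfg, delta = 3, D = NULL,
                                   standardize = FALSE) {
  stopifnot(inherits(cfg, "bggm_mcmc_config"))
  X <- as_timeseries(X)
  if (standardize) X <- standardize_timeseries(X)
  sc <- scatter_matrix(X)
  sample_posterior_scatter(sc$sigma, sc$n, theta, delta, D, cfg,
                           labels = colnames(X))
}

#' Sample the fused posterior combining time series and streamline counts
#'
#' Targets \eqn{P(G, K \mid X, S) \propto P(X\mid K) P(K\mid G) P(S\mid G)
#' P(G)}: the Dirichlet-multinomial streamline likelihood enters every edge
#' flip, so tractography evidence sharpens (or contradicts) the
#' conditional-independence structure inferred from the time series.  With
#' `alpha == beta` the streamline term is constant in \eqn{G} and the chain
#' coincides with [sample_joint_posterior()] run at the same seed.
#'
#' @inheritParams sample_joint_posterior
#' @param S A [streamline_counts()] matrix; region labels must match `X`.
#' @param alpha,beta Dirichlet concentrations for present/absent connections
#'   (defaults 1 and 0.5: high counts favor an edge while allowing
#'   tractography noise).
#' @return A `bggm_samples` object.
#' @export
sample_fused_posterior <- function(X, S, theta = 0.5, cfg, delta = 3,
                                   D = NULL, alpha = 1, beta = 0.5,
                                   standardize = FALSE) {
  stopifnot(inherits(cfg, "bggm_mcmc_config"))
  X <- as_timeseries(X)
  S <- as_streamlines(S)
  if (alpha <= 0 || beta <= 0)
    stop("`alpha` and `beta` must be positive", call. = FALSE)
  if (ncol(S) != ncol(X))
    stop("`X` and `S` have different numbers of regions", call. = FALSE)
  if (!identical(colnames(S), colnames(X)))
    stop("region labels of `X` and `S` do not match", call. = FALSE)
  if (standardize) X <- standardize_timeseries(X)
  sc <- scatter_matrix(X)
  sample_posterior_scatter(sc$sigma, sc$n, theta, delta, D, cfg,
                           S = S, alpha = alpha, beta = beta,
                           labels = colnames(X))
}

#' @export
print.bggm_samples <- function(x, ...) {
  cat(sprintf(
    "<bggm_samples> p = %d, %d draws (%d chain%s x %d), %s model\n",
    dim(x$graphs)[1], dim(x$graphs)[3], x$meta$n_chains,
    if (x$meta$n_chains > 1) "s" else "", x$meta$thin_to,
    if (x$meta$fused) "fused" else "fMRI-only"))
  cat(sprintf("  seed %d, %d iterations, burn-in %d, acceptance %s\n",
              x$meta$seed, x$meta$n_iterations, x$meta$burn_in,
              paste(sprintf("%.3f", x$meta$acceptance_rates), collapse = "/")))
  invisible(x)
}

# draws (by index) of one chain as a bggm_samples object
subset_samples <- function(samples, idx) {
  out <- samples
  out$graphs <- samples$graphs[, , idx, drop = FALSE]
  out$precisions <- samples$precisions[, , idx, drop = FALSE]
  out$chain <- samples$chain[idx]
  out
}

#' Cross-chain convergence report
#'
#' Compares per-edge inclusion probabilities across independent chains and
#' reports the maximum absolute discrepancy together with a pass/fail flag.
#'
#' @param chains Either a single `bggm_samples` object containing at least
#'   two chains, or a list of such objects (one per chain).
#' @param threshold Pass threshold on the maximum discrepancy (default
#'   0.05).
#' @return List with the per-chain edge-probability matrices
#'   (`edge_probabilities`), `max_discrepancy`, `threshold` and `passed`.
#' @export
convergence_report <- function(chains, threshold = 0.05) {
  if (inherits(chains, "bggm_samples")) {
    ids <- unique(chains$chain)
    if (length(ids) < 2L)
      stop("convergence assessment needs at least two chains", call. = FALSE)
    chains <- lapply(ids, function(ch)
      subset_samples(chains, which(chains$chain == ch)))
  }
  if (!is.list(chains) || length(chains) < 2L)
    stop("convergence assessment needs at least two chains", call. = FALSE)
  eps <- lapply(chains, function(s) apply(s$graphs, c(1, 2), mean))
  maxd <- 0
  for (a in seq_along(eps)) for (b in seq_along(eps)) if (b > a)
    maxd <- max(maxd, max(abs(eps[[a]] - eps[[b]])))
  list(edge_probabilities = eps, max_discrepancy = maxd,
       threshold = threshold, passed = maxd <= threshold)
}
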