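# Reconstruction-error measures, standardized scores, posterior-shape
# diagnostics, posterior summaries, and the exact small-p enumeration oracle.

#' Ground-truth connectivity bundle
#'
#' Pairs the true partial-correlation matrix \eqn{R^*} with the binary mask
#' \eqn{T} of true edges (1 where a connection exists, ignoring
#' directionality: the mask is symmetrized on input).  Consistency is
#' enforced: a nonzero \eqn{r^*_{ij}} requires \eqn{t_{ij} = 1}.
#'
#' @param R_star True partial-correlation matrix (unit diagonal).
#' @param T_mask Binary edge mask; defaults to the nonzero pattern of
#'   `R_star`.
#' @return An object of class `bggm_ground_truth`.
#' @export
ground_truth <- function(R_star, T_mask = NULL) {
  check_symmetric(R_star, "R_star")
  if (any(abs(diag(R_star) - 1) > 1e-8))
    stop("`R_star` must have a unit diagonal", call. = FALSE)
  p <- ncol(R_star)
  if (is.null(T_mask)) T_mask <- (R_star != 0) * 1L
  check_square(T_mask, "T_mask")
  T_mask <- 1L * ((T_mask != 0) | (t(T_mask) != 0))  # symmetrize, binarize
  diag(T_mask) <- 0L
  off <- upper.tri(R_star)
  if (any(R_star[off] != 0 & T_mask[off] == 0))
    stop("`R_star` has a nonzero entry where `T_mask` marks no edge", call. = FALSE)
  structure(list(R_star = R_star, T_mask = T_mask), class = "bggm_ground_truth")
}

#' Reconstruction-error measures against a ground truth
#'
#' With elementwise error \eqn{\Gamma = |R^* - R|}, computes the total error
#' \eqn{\eta = \frac{2}{p(p-1)}\sum_{i<j}\gamma_{ij}}, the true-positive
#' error \eqn{\eta_{tp} = N_{tp}^{-1}\sum_{i<j}\gamma_{ij} 1[t_{ij}\neq 0]}
#' and the true-negative error
#' \eqn{\eta_{tn} = N_{tn}^{-1}\sum_{i<j}\gamma_{ij} 1[t_{ij}=0]}.  When the
#' mask has no true edges (or no true non-edges) the corresponding component
#' is undefined: it is returned as `NA` with a warning rather than silently
#' zero.
#'
#' @param truth A [ground_truth()] bundle.
#' @param R Estimated partial-correlation matrix (point estimate or a single
#'   posterior draw transformed by [precision_to_partial()]).
#' @return List of class `bggm_error_scores` with `eta`, `eta_tp`, `eta_tn`.
#' @export
reconstruction_errors <- function(truth, R) {
  stopifnot(inherits(truth, "bggm_ground_truth"))
  check_square(R, "R")
  if (!all(dim(R) == dim(truth$R_star)))
    stop("dimension mismatch between `truth` and `R`", call. = FALSE)
  gam <- abs(truth$R_star - R)
  off <- upper.tri(gam)
  g <- gam[off]
  t_ij <- truth$T_mask[off]
  n_tp <- sum(t_ij != 0)
  n_tn <- sum(t_ij == 0)
  eta <- sum(g) / length(g)
  eta_tp <- if (n_tp > 0) sum(g[t_ij != 0]) / n_tp else {
    warning("no true edges in the mask: eta_tp is undefined"); NA_real_
  }
  eta_tn <- if (n_tn > 0) sum(g[t_ij == 0]) / n_tn else {
    warning("no true non-edges in the mask: eta_tn is undefined"); NA_real_
  }
  structure(list(eta = eta, eta_tp = eta_tp, eta_tn = eta_tn),
            class = "bggm_error_scores")
}

#' Standardized score of a point estimate against the posterior error cloud
#'
#' \eqn{z = (\eta_{\mathrm{point}} - \mu)/\sigma} where \eqn{\mu} and
#' \eqn{\sigma} are the mean and standard deviation of the error values
#' obtained by applying the same error measure to each posterior draw.
#'
#' @param eta_point Error of the point estimate.
#' @param eta_samples Numeric vector of per-draw errors (length >= 2 with
#'   nonzero spread).
#' @return The z-score.
#' @export
z_score <- function(eta_point, eta_samples) {
  if (length(eta_samples) < 2L)
    stop("need at least two posterior error samples", call. = FALSE)
  s <- sd(eta_samples)
  if (s == 0) stop("posterior error samples have zero spread", call. = FALSE)
  (eta_point - mean(eta_samples)) / s
}

#' Per-draw reconstruction errors of a posterior sample
#'
#' Applies [precision_to_partial()] and [reconstruction_errors()] to every
#' retained draw, yielding the posterior error distribution \eqn{P(\eta)}
#' used by [z_score()].
#'
#' @param samples A `bggm_samples` object.
#' @param truth A [ground_truth()] bundle.
#' @param component Which error to extract: `"eta"`, `"eta_tp"` or
#'   `"eta_tn"`.
#' @return Numeric vector, one error per retained draw.
#' @export
eta_distribution <- function(samples, truth, component = c("eta", "eta_tp", "eta_tn")) {
  stopifnot(inherits(samples, "bggm_samples"))
  component <- match.arg(component)
  vapply(seq_len(dim(samples$precisions)[3]), function(s) {
    R <- precision_to_partial(samples$precisions[, , s])
    reconstruction_errors(truth, R)[[component]]
  }, numeric(1))
}

#' Plug-in entropy of the posterior graph distribution
#'
#' \eqn{H = -\sum_G f(G)\log_2 f(G)} over the empirical frequencies
#' \eqn{f(G)} of the distinct graphs among the retained draws, in bits.  A
#' chain locked on a single graph has entropy 0; a uniform spread over
#' \eqn{2^k} distinct graphs has entropy \eqn{k} bits.
#'
#' @param samples A `bggm_samples` object.
#' @return Entropy in bits.
#' @export
posterior_entropy <- function(samples) {
  stopifnot(inherits(samples, "bggm_samples"))
  bits <- apply(samples$graphs, 3, graph_bits)
  f <- tabulate(factor(bits)) / length(bits)
  -sum(f * log2(f)) + 0  # + 0 avoids returning negative zero
}

#' Maximum a posteriori graph and its empirical probability
#'
#' Returns the modal graph among the retained draws together with its
#' empirical frequency.  Ties are broken by first occurrence; all tied
#' graphs are reported.
#'
#' @param samples A `bggm_samples` object.
#' @return List with `graph` (adjacency matrix), `probability`, and `ties`
#'   (list of all graphs attaining the mode).
#' @export
map_probability <- function(samples) {
  stopifnot(inherits(samples, "bggm_samples"))
  bits <- apply(samples$graphs, 3, graph_bits)
  counts <- table(factor(bits, levels = unique(bits)))  # first-occurrence order
  top <- max(counts)
  tied <- names(counts)[counts == top]
  p <- dim(samples$graphs)[1]
  list(graph = bits_to_graph(tied[1], p, samples$region_labels),
       probability = as.numeric(top) / length(bits),
       ties = lapply(tied, bits_to_graph, p = p,
                     labels = samples$region_labels))
}

#' Posterior summary matrices
#'
#' Edge-inclusion probabilities (fraction of draws containing each edge),
#' the posterior mean and per-edge variance of the partial correlations
#' (each draw transformed first), and the mean graph density.
#'
#' @param samples A `bggm_samples` object.
#' @return List with `edge_probabilities`, `partial_mean`,
#'   `partial_variance` (population variance over draws) and `density`.
#' @export
posterior_summaries <- function(samples) {
  stopifnot(inherits(samples, "bggm_samples"))
  p <- dim(samples$graphs)[1]
  nT <- dim(samples$graphs)[3]
  ep <- apply(samples$graphs, c(1, 2), mean)
  Rsum <- matrix(0, p, p); R2sum <- matrix(0, p, p)
  for (s in seq_len(nT)) {
    R <- precision_to_partial(samples$precisions[, , s])
    Rsum <- Rsum + R
    R2sum <- R2sum + R^2
  }
  pm <- Rsum / nT
  pv <- R2sum / nT - pm^2
  pv[pv < 0] <- 0
  labels <- samples$region_labels
  dimnames(ep) <- dimnames(pm) <- dimnames(pv) <- list(labels, labels)
  list(edge_probabilities = ep, partial_mean = pm, partial_variance = pv,
       density = mean(apply(samples$graphs, 3, function(g) sum(g) / (p * (p - 1)))))
}

#' Ranking quality of edge probabilities against a true mask
#'
#' Area under the ROC curve of the posterior edge-inclusion probabilities as
#' a score separating true edges from true non-edges, computed by the
#' rank-sum (Mann-Whitney) formula with midranks for ties.
#'
#' @param truth A [ground_truth()] bundle (or binary mask matrix).
#' @param edge_probabilities Symmetric matrix of edge scores.
#' @return AUC in \[0, 1\].
#' @export
edge_roc_auc <- function(truth, edge_probabilities) {
  mask <- if (inherits(truth, "bggm_ground_truth")) truth$T_mask else truth
  off <- upper.tri(mask)
  y <- mask[off] != 0
  x <- edge_probabilities[off]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both true edges and true non-edges", call. = FALSE)
  r <- rank(x)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exact posterior edge probabilities by graph enumeration (small p)
#'
#' For \eqn{p \le 4}, enumerates all \eqn{2^{p(p-1)/2}} graphs, computes each
#' marginal likelihood through the conjugacy identity
#' \eqn{P(X\mid G) = (2\pi)^{-np/2} Z_G(\delta+n, D+\Sigma) / Z_G(\delta,D)}
#' (closed form for decomposable graphs, Monte Carlo otherwise), combines
#' with the Bernoulli edge prior and normalizes.  Serves as the independent
#' oracle against which the MCMC is validated.
#'
#' @inheritParams sample_joint_posterior
#' @param mc_samples Monte-Carlo sample size for non-decomposable
#'   normalizing constants (default 1e5).
#' @param seed Seed for those Monte-Carlo estimates.
#' @return List with `edge_probabilities` (exact posterior edge-inclusion
#'   matrix), `log_posterior` (named vector over graph bitstrings, canonical
#'   column-major upper-triangle order) and `log_marginal` (model evidence).
#' @export
exact_small_p_posterior <- function(X, theta = 0.5, delta = 3, D = NULL,
                                    standardize = FALSE, mc_samples = 1e5,
                                    seed = 1L) {
  X <- as_timeseries(X)
  if (standardize) X <- standardize_timeseries(X)
  p <- ncol(X)
  if (p > 4L) stop("exact enumeration is limited to p <= 4", call. = FALSE)
  sc <- scatter_matrix(X)
  theta <- as_edge_prior(theta, p, colnames(X))
  if (is.null(D)) D <- diag(p)
  npairs <- p * (p - 1) / 2
  ut <- which(upper.tri(matrix(0, p, p)))
  ngraph <- 2^npairs
  logpost <- numeric(ngraph)
  bits_all <- character(ngraph)
  inc <- matrix(0, p, p)
  for (gidx in seq_len(ngraph) - 1L) {
    bits <- as.integer(intToBits(gidx))[seq_len(npairs)]
    G <- matrix(0L, p, p)
    G[ut] <- bits
    G <- G + t(G)
    lp <- graph_log_prior(G, theta)
    if (is.finite(lp)) {
      prior <- gwishart_params(G, delta, D)
      post <- gwishart_params(G, delta + sc$n, D + sc$sigma)
      lz0 <- log_normalizing_constant(prior, mc_samples, seed)$log_z
      lz1 <- log_normalizing_constant(post, mc_samples, seed + 1L)$log_z
      lp <- lp + lz1 - lz0 - (sc$n * p / 2) * log(2 * pi)
    }
    logpost[gidx + 1L] <- lp
    bits_all[gidx + 1L] <- paste(bits, collapse = "")
  }
  lse <- logsumexp(logpost)
  w <- exp(logpost - lse)
  for (gidx in seq_len(ngraph)) {
    bits <- as.integer(strsplit(bits_all[gidx], "")[[1]])
    G <- matrix(0L, p, p)
    G[ut] <- bits
    inc <- inc + w[gidx] * (G + t(G))
  }
  dimnames(inc) <- list(colnames(X), colnames(X))
  names(logpost) <- bits_all
  list(edge_probabilities = inc, log_posterior = logpost - lse,
       log_marginal = lse)
}
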