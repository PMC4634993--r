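# G-Wishart distribution: kernel density, conjugate update, direct sampling,
# chordality test, and normalizing constants (closed-form for decomposable
# graphs, Monte Carlo otherwise).

#' G-Wishart parameter bundle
#'
#' Holds the degrees of freedom \eqn{\delta}, scale matrix \eqn{D} and the
#' graph constraining the support to \eqn{P_G}, the cone of positive-definite
#' matrices with zeros at every non-edge.  The defaults \eqn{\delta = 3},
#' \eqn{D = I_p} give the vague prior used throughout the package.
#'
#' @param graph Binary symmetric adjacency matrix (zero diagonal).
#' @param delta Degrees of freedom, must be positive (default 3).
#' @param D Symmetric positive-definite scale matrix (default identity).
#' @return An object of class `bggm_gwishart`.
#' @examples
#' gwishart_params(empty_graph(3))
#' @export
gwishart_params <- function(graph, delta = 3, D = NULL) {
  graph <- validate_graph(graph)
  p <- ncol(graph)
  if (is.null(D)) D <- diag(p)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("`delta` must be a positive scalar", call. = FALSE)
  if (!all(dim(D) == p)) stop("`D` and `graph` dimensions differ", call. = FALSE)
  check_pd(D, "D")
  structure(list(delta = delta, D = D, graph = graph), class = "bggm_gwishart")
}

#' @export
print.bggm_gwishart <- function(x, ...) {
  cat(sprintf("<bggm_gwishart> p = %d, delta = %g, %d edges\n",
              ncol(x$graph), x$delta, sum(x$graph) / 2))
  invisible(x)
}

#' Empty graph on p nodes
#' @param p Number of nodes.
#' @param labels Optional node labels.
#' @return p x p zero adjacency matrix.
#' @export
empty_graph <- function(p, labels = NULL) {
  g <- matrix(0L, p, p)
  labels <- labels %||% paste0("V", seq_len(p))
  dimnames(g) <- list(labels, labels)
  g
}

#' Complete graph on p nodes
#' @inheritParams empty_graph
#' @return p x p adjacency matrix with all off-diagonal entries 1.
#' @export
full_graph <- function(p, labels = NULL) {
  g <- matrix(1L, p, p); diag(g) <- 0L
  labels <- labels %||% paste0("V", seq_len(p))
  dimnames(g) <- list(labels, labels)
  g
}

#' Unnormalized G-Wishart log density
#'
#' Evaluates the kernel
#' \eqn{\frac{\delta-2}{2}\log|K| - \frac12\langle K, D\rangle} of the
#' G-Wishart distribution.  The normalizing constant \eqn{Z_G(\delta, D)} is
#' not included; see [log_normalizing_constant()].  `K` must be positive
#' definite and respect the zero pattern of the graph exactly; a violation is
#' treated as a programming error rather than a zero-density point.
#'
#' @param K Precision matrix in \eqn{P_G}.
#' @param params A [gwishart_params()] bundle.
#' @return Scalar log kernel value.
#' @export
gwishart_unnorm_log_density <- function(K, params) {
  stopifnot(inherits(params, "bggm_gwishart"))
  if (!all(dim(K) == dim(params$D)))
    stop("dimension mismatch between `K` and `params`", call. = FALSE)
  ch <- check_pd(K)
  off <- params$graph == 0L & upper.tri(params$graph)
  if (any(K[off] != 0))
    stop("`K` has nonzero entries off the graph's edge set", call. = FALSE)
  logdet <- 2 * sum(log(diag(ch)))
  ((params$delta - 2) / 2) * logdet - 0.5 * sum(K * params$D)
}

#' Conjugate posterior update of G-Wishart parameters
#'
#' The G-Wishart prior is conjugate to the zero-mean Gaussian likelihood:
#' observing a scatter matrix \eqn{\Sigma} from \eqn{n} samples maps
#' \eqn{(\delta, D) \mapsto (\delta + n, D + \Sigma)} with the graph
#' unchanged.
#'
#' @param params A [gwishart_params()] bundle (the prior).
#' @param Sigma A [scatter_matrix()] object, or raw matrix with `n` given.
#' @param n Sample count when `Sigma` is a raw matrix.
#' @return Updated `bggm_gwishart` parameters.
#' @export
gwishart_posterior_params <- function(params, Sigma, n = NULL) {
  stopifnot(inherits(params, "bggm_gwishart"))
  Sigma <- as_scatter(Sigma, n)
  if (!all(dim(Sigma$sigma) == dim(params$D)))
    stop("dimension mismatch between `Sigma` and `params`", call. = FALSE)
  gwishart_params(params$graph, params$delta + Sigma$n, params$D + Sigma$sigma)
}

#' Draw precision matrices from a G-Wishart distribution
#'
#' Direct sampler: an unconstrained Wishart draw with degrees of freedom
#' \eqn{\delta + p - 1} and scale \eqn{D^{-1}} is projected onto \eqn{P_G} by
#' block-coordinate completion of its covariance (iterated until the working
#' covariance stabilizes), after which non-edge entries are exactly zeroed.
#' For the complete graph this reduces to an ordinary Wishart draw, and for
#' the empty graph the diagonal elements are independent
#' \eqn{\mathrm{Gamma}(\delta/2, d_{ii}/2)} variates.
#'
#' @param params A [gwishart_params()] bundle.
#' @param count Number of draws.
#' @param seed Integer seed (mandatory; draws are reproducible).
#' @param tol Relative convergence tolerance of the completion loop.
#' @param maxit Maximum completion sweeps before erroring.
#' @return List of `count` positive-definite matrices, each with zeros
#'   exactly off the graph's edge set.
#' @examples
#' K <- gwishart_sample(gwishart_params(empty_graph(3)), 2, seed = 1)
#' K[[1]]
#' @export
gwishart_sample <- function(params, count, seed, tol = 1e-8, maxit = 1000L) {
  stopifnot(inherits(params, "bggm_gwishart"))
  if (count < 1L) stop("`count` must be at least 1", call. = FALSE)
  adj <- matrix(as.integer(params$graph != 0L), nrow(params$graph))
  draws <- with_seed(seed,
    .rgwish_cpp(adj, params$delta, params$D, as.integer(count), tol,
                as.integer(maxit)))
  labels <- colnames(params$graph)
  lapply(seq_len(count), function(s) {
    K <- draws[, , s]
    dimnames(K) <- list(labels, labels)
    K
  })
}

#' Test whether a graph is decomposable (chordal)
#'
#' Decomposable graphs admit a closed-form G-Wishart normalizing constant via
#' their clique/separator factorization.  The test is delegated to a
#' maximum-cardinality search.
#'
#' @param G Binary symmetric adjacency matrix.
#' @return `TRUE` iff the graph is chordal.
#' @export
is_decomposable <- function(G) {
  G <- validate_graph(G)
  ig <- igraph::graph_from_adjacency_matrix(G, mode = "undirected")
  igraph::is_chordal(ig)$chordal
}

# Maximal cliques and RIP-ordered separators of a chordal graph.
clique_separators <- function(G) {
  ig <- igraph::graph_from_adjacency_matrix(G, mode = "undirected")
  cl <- lapply(igraph::max_cliques(ig), as.integer)
  # order cliques by their highest vertex in a perfect (MCS) ordering, then
  # take running-intersection separators
  rank <- igraph::max_cardinality(ig)$alpha
  cl <- cl[order(vapply(cl, function(C) max(rank[C]), numeric(1)))]
  seps <- list()
  seen <- integer(0)
  for (k in seq_along(cl)) {
    if (k > 1L) {
      s <- intersect(cl[[k]], seen)
      if (length(s)) seps[[length(seps) + 1L]] <- s
    }
    seen <- union(seen, cl[[k]])
  }
  list(cliques = cl, separators = seps)
}

# log multivariate gamma
lmgamma <- function(p, a) {
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a - (seq_len(p) - 1) / 2))
}

# Closed-form log Z for the complete graph on k nodes:
# Z = 2^{nu k/2} Gamma_k(nu/2) |D|^{-nu/2},  nu = delta + k - 1.
log_z_complete <- function(delta, D) {
  D <- as.matrix(D)
  k <- nrow(D)
  nu <- delta + k - 1
  (nu * k / 2) * log(2) + lmgamma(k, nu / 2) -
    (nu / 2) * as.numeric(determinant(D)$modulus)
}

#' Log normalizing constant of a G-Wishart distribution
#'
#' For a decomposable graph the constant factorizes exactly over the maximal
#' cliques and separators of a junction tree,
#' \eqn{Z_G = \prod_C Z(\delta, D_C) / \prod_S Z(\delta, D_S)}, each factor a
#' complete-graph (Wishart) constant; the reported standard error is then 0.
#' For non-decomposable graphs a Monte-Carlo estimator in the free-element
#' Cholesky parameterization is used and its standard error (on the log
#' scale, delta method) is reported.
#'
#' @param params A [gwishart_params()] bundle.
#' @param mc_samples Monte-Carlo sample size for non-decomposable graphs.
#' @param seed Seed for the Monte-Carlo estimator.
#' @return List with elements `log_z` and `se`.
#' @export
log_normalizing_constant <- function(params, mc_samples = 10000L, seed = 1L) {
  stopifnot(inherits(params, "bggm_gwishart"))
  G <- params$graph
  if (is_decomposable(G)) {
    cs <- clique_separators(G)
    v <- sum(vapply(cs$cliques, function(C)
      log_z_complete(params$delta, params$D[C, C, drop = FALSE]), numeric(1)))
    if (length(cs$separators))
      v <- v - sum(vapply(cs$separators, function(S)
        log_z_complete(params$delta, params$D[S, S, drop = FALSE]), numeric(1)))
    return(list(log_z = v, se = 0))
  }
  if (mc_samples < 1L)
    stop("`mc_samples` must be >= 1 for a non-decomposable graph", call. = FALSE)
  est <- with_seed(seed,
    .gwish_logz_mc_cpp(matrix(as.integer(G != 0L), nrow(G)), params$delta,
                       params$D, as.integer(mc_samples)))
  list(log_z = est[1], se = est[2])
}
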