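# Prior distributions over graphs: independent Bernoulli edge prior and the
# hemisphere/homotopy-informed prior.

#' Construct an edge-prior probability matrix
#'
#' Builds the symmetric matrix \eqn{\Theta} of prior edge-inclusion
#' probabilities \eqn{\theta_{ij} \in [0,1]}.  A scalar is expanded to all
#' pairs; a matrix is symmetrized from its upper triangle (the upper triangle
#' is authoritative).  Entries of exactly 0 or 1 act as hard constraints
#' downstream: the MCMC never proposes flipping such pairs.
#'
#' @param theta Scalar in \[0,1\] or a p x p matrix of probabilities.
#' @param p Number of regions (required when `theta` is scalar).
#' @param labels Optional region labels.
#' @return A p x p symmetric matrix of class `bggm_edge_prior`.
#' @examples
#' edge_prior(0.5, p = 3)
#' @export
edge_prior <- function(theta, p = NULL, labels = NULL) {
  if (length(theta) == 1L) {
    if (is.null(p)) stop("`p` is required for a scalar `theta`", call. = FALSE)
    theta <- matrix(theta, p, p)
  }
  check_square(theta, "theta")
  if (any(is.na(theta)) || any(theta < 0) || any(theta > 1))
    stop("edge-prior probabilities must lie in [0, 1]", call. = FALSE)
  up <- theta
  up[lower.tri(up)] <- t(up)[lower.tri(up)]  # mirror the upper triangle
  diag(up) <- 0
  labels <- labels %||% colnames(theta) %||% paste0("V", seq_len(ncol(theta)))
  dimnames(up) <- list(labels, labels)
  structure(up, class = c("bggm_edge_prior", class(up)))
}

as_edge_prior <- function(theta, p, labels = NULL) {
  if (inherits(theta, "bggm_edge_prior")) {
    if (nrow(theta) != p) stop("edge prior has the wrong dimension", call. = FALSE)
    return(theta)
  }
  edge_prior(theta, p = p, labels = labels)
}

#' Log prior probability of a graph under independent Bernoulli edges
#'
#' \eqn{\log P(G\mid\Theta) = \sum_{i<j} g_{ij}\log\theta_{ij} +
#' (1-g_{ij})\log(1-\theta_{ij})}.  Returns `-Inf` when the graph contradicts
#' a hard 0/1 prior entry.
#'
#' @param G Binary symmetric adjacency matrix, zero diagonal.
#' @param theta An [edge_prior()] (or scalar/matrix coercible to one).
#' @return Scalar log prior (possibly `-Inf`).
#' @export
graph_log_prior <- function(G, theta) {
  G <- validate_graph(G)
  p <- ncol(G)
  theta <- as_edge_prior(theta, p)
  ut <- upper.tri(G)
  g <- G[ut]; th <- theta[ut]
  terms <- numeric(length(g))
  terms[g == 1] <- log(th[g == 1])
  terms[g == 0] <- log1p(-th[g == 0])
  sum(terms)
}

validate_graph <- function(G) {
  check_square(G, "G")
  if (any(G != 0 & G != 1)) stop("adjacency must be binary", call. = FALSE)
  if (any(diag(G) != 0)) stop("adjacency must have a zero diagonal", call. = FALSE)
  if (any(G != t(G))) stop("adjacency must be symmetric", call. = FALSE)
  storage.mode(G) <- "integer"
  G
}

#' Hemisphere and homotopy annotation of regions
#'
#' @param hemisphere Character vector of `"left"`/`"right"` labels, one per
#'   region.
#' @param homotopes Two-column matrix or data frame of region indices (or
#'   names) pairing each region with its homotope in the other hemisphere.
#'   Pairs must be mutual and cross-hemisphere; a region may appear in at
#'   most one pair.
#' @param labels Optional region names.
#' @return An object of class `bggm_region_annotation`.
#' @export
region_annotation <- function(hemisphere, homotopes = NULL, labels = NULL) {
  hemisphere <- match.arg(tolower(hemisphere), c("left", "right"),
                          several.ok = TRUE)
  p <- length(hemisphere)
  labels <- labels %||% paste0("V", seq_len(p))
  pairs <- NULL
  if (!is.null(homotopes)) {
    pairs <- as.matrix(homotopes)
    if (ncol(pairs) != 2L) stop("`homotopes` needs two columns", call. = FALSE)
    if (is.character(pairs)) {
      pairs <- matrix(match(pairs, labels), ncol = 2L)
      if (anyNA(pairs)) stop("unknown region name in `homotopes`", call. = FALSE)
    }
    storage.mode(pairs) <- "integer"
    if (any(pairs < 1L | pairs > p)) stop("homotopy index out of range", call. = FALSE)
    if (anyDuplicated(as.vector(pairs)))
      stop("a region may appear in at most one homotopy pair", call. = FALSE)
    same <- hemisphere[pairs[, 1]] == hemisphere[pairs[, 2]]
    if (any(same))
      stop("homotopy pairs must join regions in different hemispheres", call. = FALSE)
  }
  structure(list(hemisphere = hemisphere, homotopes = pairs, labels = labels),
            class = "bggm_region_annotation")
}

#' Homotopy-informed edge prior
#'
#' Encodes the assumption that homotopic regions in opposite hemispheres are
#' directly connected while all other interhemispheric connections are
#' absent; within a hemisphere the prior stays agnostic:
#' \eqn{\theta_{ij}} is `within_theta` for same-hemisphere pairs, 1 for
#' homotopic pairs and 0 for the remaining cross-hemisphere pairs.  The 0/1
#' entries are hard constraints for the sampler.
#'
#' @param annotation A [region_annotation()].
#' @param within_theta Prior probability for same-hemisphere pairs
#'   (default 0.5).
#' @return An [edge_prior()] matrix.
#' @export
homotopy_prior <- function(annotation, within_theta = 0.5) {
  if (!inherits(annotation, "bggm_region_annotation"))
    stop("`annotation` must be a region_annotation", call. = FALSE)
  if (within_theta < 0 || within_theta > 1)
    stop("`within_theta` must lie in [0, 1]", call. = FALSE)
  hemi <- annotation$hemisphere
  p <- length(hemi)
  th <- matrix(0, p, p)
  same <- outer(hemi, hemi, "==")
  th[same] <- within_theta
  if (!is.null(annotation$homotopes))
    for (r in seq_len(nrow(annotation$homotopes))) {
      i <- annotation$homotopes[r, 1]; j <- annotation$homotopes[r, 2]
      th[i, j] <- th[j, i] <- 1
    }
  diag(th) <- 0
  edge_prior(th, labels = annotation$labels)
}
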