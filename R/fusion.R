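# Dirichlet-multinomial likelihood linking probabilistic-tractography
# streamline counts to the conditional-independence graph.

#' Streamline-count matrix
#'
#' Validates a p x p matrix of nonnegative integer streamline counts with a
#' zero diagonal.  Row j holds the counts of probabilistic streamlines seeded
#' in region j that reach each other region; rows need not be symmetric.
#'
#' @param counts Integer-valued p x p matrix, zero diagonal.
#' @param labels Optional region labels.
#' @return Validated integer matrix of class `bggm_streamlines`.
#' @export
streamline_counts <- function(counts, labels = NULL) {
  check_square(counts, "counts")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("streamline counts must be nonnegative integers (offending cell [%d, %d])",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (any(diag(counts) != 0))
    stop("streamline counts must have a zero diagonal", call. = FALSE)
  storage.mode(counts) <- "integer"
  labels <- labels %||% colnames(counts) %||% paste0("V", seq_len(ncol(counts)))
  dimnames(counts) <- list(labels, labels)
  structure(counts, class = c("bggm_streamlines", class(counts)))
}

as_streamlines <- function(S) {
  if (inherits(S, "bggm_streamlines")) return(S)
  streamline_counts(as.matrix(S))
}

#' Dirichlet-multinomial log likelihood of streamline counts given a graph
#'
#' Each row j of the count matrix is modeled as a Dirichlet-multinomial draw
#' over the other \eqn{p-1} regions with concentration
#' \eqn{a_{ji} = \alpha g_{ij} + \beta(1 - g_{ij})}: streamlines concentrate
#' on targets that are graph neighbors when \eqn{\alpha > \beta}.  Rows are
#' independent given the graph, and each row reads its concentrations off
#' the corresponding column of the symmetric adjacency, so one edge informs
#' both endpoint rows.  The multinomial coefficient is included, making each
#' row term a true probability (it is constant in \eqn{G}, so inference is
#' unaffected); a row with total count zero contributes 0.
#'
#' @param S A [streamline_counts()] matrix.
#' @param G Binary symmetric adjacency matrix.
#' @param alpha Concentration on edges (default 1); must be positive.
#' @param beta Concentration on non-edges (default 0.5); must be positive.
#' @return Scalar log likelihood (finite for all valid inputs).
#' @export
dirmult_log_likelihood <- function(S, G, alpha = 1, beta = 0.5) {
  S <- as_streamlines(S)
  G <- validate_graph(G)
  if (!all(dim(S) == dim(G)))
    stop("dimensions of `S` and `G` do not match", call. = FALSE)
  if (alpha <= 0 || beta <= 0)
    stop("`alpha` and `beta` must be positive", call. = FALSE)
  p <- ncol(G)
  ll <- 0
  for (j in seq_len(p)) {
    s <- S[j, -j]
    a <- ifelse(G[j, -j] == 1L, alpha, beta)
    N <- sum(s)
    if (N == 0) next
    A <- sum(a)
    ll <- ll + lgamma(N + 1) - sum(lgamma(s + 1)) +
      lgamma(A) - lgamma(A + N) + sum(lgamma(a + s) - lgamma(a))
  }
  ll
}
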