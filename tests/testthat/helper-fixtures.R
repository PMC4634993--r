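# Shared fixture builders; everything is generated in code.

# random PD matrix with unit-order eigenvalues
rand_pd <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p)
}

# build a bggm_samples object from a list of adjacency matrices and
# (optionally) matching precision matrices -- for diagnostics fixtures
manual_samples <- function(graphs, precisions = NULL, chain = NULL) {
  p <- nrow(graphs[[1]])
  nT <- length(graphs)
  garr <- array(0L, dim = c(p, p, nT))
  karr <- array(0, dim = c(p, p, nT))
  for (s in seq_len(nT)) {
    garr[, , s] <- graphs[[s]]
    karr[, , s] <- if (is.null(precisions)) diag(p) else precisions[[s]]
  }
  structure(list(
    graphs = garr, precisions = karr,
    chain = chain %||% rep(1L, nT),
    region_labels = paste0("V", seq_len(p)),
    meta = list(seed = 0L, n_iterations = nT, burn_in = 0L, thin_to = nT,
                n_chains = length(unique(chain %||% 1L)), fused = FALSE,
                delta = 3, alpha = NA_real_, beta = NA_real_,
                acceptance_rates = NA_real_)),
    class = "bggm_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# graph on p nodes from upper-triangle bits (column-major order)
graph_from_bits <- function(bits, p) {
  g <- matrix(0L, p, p)
  g[upper.tri(g)] <- bits
  g + t(g)
}

# all count vectors of length k summing to total
compositions <- function(total, k) {
  if (k == 1) return(matrix(total, 1, 1))
  out <- NULL
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}
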