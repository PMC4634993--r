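# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.  All exported stochastic functions funnel
# their seeds through here so the package never perturbs the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# canonical pair ordering: column-major upper triangle (1,2),(1,3),(2,3),...
pair_index <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}

# serialize a graph as an upper-triangle bitstring in canonical pair order
graph_bits <- function(adj) {
  paste(adj[upper.tri(adj)], collapse = "")
}

bits_to_graph <- function(bits, p, labels = NULL) {
  g <- matrix(0L, p, p)
  g[upper.tri(g)] <- as.integer(strsplit(bits, "")[[1]])
  g <- g + t(g)
  dimnames(g) <- list(labels, labels)
  g
}

check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("`%s` must be a square matrix", what), call. = FALSE)
  invisible(m)
}

check_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  check_square(m, what)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop(sprintf("`%s` must be symmetric", what), call. = FALSE)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
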