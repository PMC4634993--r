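# Readers/writers for the package's file artifacts, structured run
# configuration, and the end-to-end pipeline.
#
# All matrices travel as delimited text with one header row of region
# labels; the delimiter (comma, tab, semicolon or whitespace) is
# autodetected.  Posterior graph draws are serialized as upper-triangle
# bitstrings, one per line, in column-major pair order.

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L)
  for (d in c(",", "\t", ";")) if (grepl(d, line, fixed = TRUE)) return(d)
  ""
}

#' Read a typed matrix from a delimited text file
#'
#' @param path File path; first row must hold region labels.
#' @param kind One of `"timeseries"` (n x p observation matrix),
#'   `"counts"` (square nonnegative integer streamline matrix, zero
#'   diagonal), `"prior"` (square matrix of probabilities in \[0,1\]) or
#'   `"mask"` (square binary matrix).
#' @return The validated object: a [timeseries_data()], a
#'   [streamline_counts()], an [edge_prior()] or a binary matrix.
#' @export
read_matrix <- function(path, kind = c("timeseries", "counts", "prior", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- sniff_delim(path)
  m <- as.matrix(read.table(path, header = TRUE, sep = d,
                            check.names = FALSE, row.names = NULL))
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  switch(kind,
    timeseries = timeseries_data(m),
    counts = streamline_counts(m, colnames(m)),
    prior = {
      if (any(m < 0 | m > 1)) {
        bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
        stop(sprintf("prior entry out of [0, 1] at row %d, column %d",
                     bad[1], bad[2]), call. = FALSE)
      }
      edge_prior(m)
    },
    mask = {
      if (any(m != 0 & m != 1)) {
        bad <- which(m != 0 & m != 1, arr.ind = TRUE)[1, ]
        stop(sprintf("mask entry not 0/1 at row %d, column %d",
                     bad[1], bad[2]), call. = FALSE)
      }
      storage.mode(m) <- "integer"
      m
    })
}

#' Write a matrix as delimited text with a label header
#'
#' @param m Matrix to write.
#' @param path Destination path.
#' @param sep Field delimiter (default comma).
#' @export
write_matrix <- function(m, path, sep = ",") {
  m <- as.matrix(m)
  colnames(m) <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  # full precision so that write-then-read round-trips bit-identically
  fm <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  write.table(fm, path, sep = sep, row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Read a structured run configuration
#'
#' YAML is the canonical format; JSON is accepted as well (chosen by file
#' extension).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

resolve_theta <- function(cfg, X) {
  p <- ncol(X)
  if (!is.null(cfg$theta_file)) return(read_matrix(cfg$theta_file, "prior"))
  if (!is.null(cfg$annotation_file)) {
    ann <- read.table(cfg$annotation_file, header = TRUE,
                      sep = sniff_delim(cfg$annotation_file),
                      check.names = FALSE, stringsAsFactors = FALSE)
    pairs <- NULL
    if (!is.null(cfg$homotopy_file))
      pairs <- as.matrix(read.table(cfg$homotopy_file, header = FALSE,
                                    sep = sniff_delim(cfg$homotopy_file),
                                    stringsAsFactors = FALSE))
    ord <- match(colnames(X), ann[[1]])
    if (anyNA(ord))
      stop("annotation file does not cover all regions", call. = FALSE)
    return(homotopy_prior(
      region_annotation(ann[[2]][ord], homotopes = pairs,
                        labels = colnames(X)),
      within_theta = cfg$within_theta %||% 0.5))
  }
  edge_prior(cfg$theta %||% 0.5, p = p, labels = colnames(X))
}

#' Run the full inference pipeline from a configuration
#'
#' Reads the inputs named in the configuration, runs the plain or fused
#' posterior sampler, and writes posterior samples, summary matrices,
#' diagnostics and a reproducibility manifest to the output directory.  A
#' failed cross-chain convergence check is recorded as a warning in the
#' manifest; outputs are still written.
#'
#' Recognized keys: `timeseries` (path, required), `streamlines`,
#' `theta` | `theta_file` | `annotation_file` + `homotopy_file` +
#' `within_theta`, `delta`, `D_file`, `alpha`, `beta`, `n_iterations`,
#' `burn_in`, `thin_to`, `n_chains`, `seed` (required), `standardize`,
#' `output_dir` (required).
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return Invisibly, the manifest list.  Files written:
#'   `edge_probabilities.csv`, `partial_mean.csv`, `partial_variance.csv`,
#'   `graphs.txt`, `precisions.txt` + `precisions_index.json`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$timeseries) || is.null(cfg$seed) || is.null(cfg$output_dir))
    stop("config must name `timeseries`, `seed` and `output_dir`", call. = FALSE)
  X <- read_matrix(cfg$timeseries, "timeseries")
  theta <- resolve_theta(cfg, X)
  D <- if (!is.null(cfg$D_file)) {
    m <- as.matrix(read.table(cfg$D_file, header = TRUE, check.names = FALSE,
                              sep = sniff_delim(cfg$D_file)))
    storage.mode(m) <- "double"; m
  } else NULL
  mcfg <- mcmc_config(
    n_iterations = cfg$n_iterations %||% 50000L,
    burn_in = cfg$burn_in,
    thin_to = cfg$thin_to %||% 1000L,
    n_chains = cfg$n_chains %||% 2L,
    seed = cfg$seed)
  fused <- !is.null(cfg$streamlines)
  samples <- if (fused) {
    S <- read_matrix(cfg$streamlines, "counts")
    sample_fused_posterior(X, S, theta, mcfg, delta = cfg$delta %||% 3,
                           D = D, alpha = cfg$alpha %||% 1,
                           beta = cfg$beta %||% 0.5,
                           standardize = isTRUE(cfg$standardize))
  } else {
    sample_joint_posterior(X, theta, mcfg, delta = cfg$delta %||% 3, D = D,
                           standardize = isTRUE(cfg$standardize))
  }

  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sm <- posterior_summaries(samples)
  write_matrix(sm$edge_probabilities, file.path(out, "edge_probabilities.csv"))
  write_matrix(sm$partial_mean, file.path(out, "partial_mean.csv"))
  write_matrix(sm$partial_variance, file.path(out, "partial_variance.csv"))
  writeLines(apply(samples$graphs, 3, graph_bits), file.path(out, "graphs.txt"))

  p <- dim(samples$precisions)[1]
  nT <- dim(samples$precisions)[3]
  flat <- t(apply(samples$precisions, 3, as.vector))  # one row-major draw per row
  write.table(flat, file.path(out, "precisions.txt"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(p = p, draws = nT, layout = "one draw per line, p*p column-major entries",
         chain = samples$chain, region_labels = samples$region_labels),
    file.path(out, "precisions_index.json"), auto_unbox = TRUE)

  conv <- if (mcfg$n_chains >= 2L) convergence_report(samples) else NULL
  warnings <- character(0)
  if (!is.null(conv) && !conv$passed)
    warnings <- c(warnings, sprintf(
      "cross-chain edge-probability discrepancy %.3f exceeds %.2f",
      conv$max_discrepancy, conv$threshold))
  for (w in warnings) warning(w, call. = FALSE)

  manifest <- list(
    package = "bggm", version = as.character(packageVersion("bggm")),
    mode = if (fused) "fused" else "fmri_only",
    config = cfg,
    diagnostics = list(
      entropy_bits = posterior_entropy(samples),
      map_probability = map_probability(samples)$probability,
      mean_density = sm$density,
      acceptance_rates = samples$meta$acceptance_rates,
      convergence_max_discrepancy = if (is.null(conv)) NA else conv$max_discrepancy,
      convergence_passed = if (is.null(conv)) NA else conv$passed,
      warnings = warnings))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read posterior graph draws written by [run_pipeline()]
#'
#' @param path Path to a `graphs.txt` file of upper-triangle bitstrings.
#' @param labels Optional region labels.
#' @return 3-d array of adjacency matrices.
#' @export
read_posterior_graphs <- function(path, labels = NULL) {
  bits <- readLines(path)
  npairs <- nchar(bits[1])
  p <- (1 + sqrt(1 + 8 * npairs)) / 2
  if (p != round(p)) stop("bitstring length is not a triangular number", call. = FALSE)
  arr <- array(0L, dim = c(p, p, length(bits)))
  for (s in seq_along(bits)) arr[, , s] <- bits_to_graph(bits[s], p, labels)
  arr
}
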