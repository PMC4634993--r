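# Core domain types and operations: time-series container, scatter matrix,
# Gaussian likelihood, and the precision -> partial-correlation transform.

#' Construct a region-by-time-point data object
#'
#' Wraps an \eqn{n \times p} numeric matrix of observations (rows are time
#' points, columns are regions) together with region labels and a flag
#' recording whether the columns have been standardized to zero mean and unit
#' variance.
#'
#' @param values Numeric matrix, \eqn{n \ge 1} rows and \eqn{p \ge 2} columns,
#'   no missing values.
#' @param region_labels Character vector of length \eqn{p}; defaults to the
#'   column names of `values` or `V1..Vp`.
#' @param standardized Logical; set by [standardize_timeseries()].
#' @return An object of class `bggm_timeseries`: the data matrix with label
#'   and standardization attributes.
#' @examples
#' X <- timeseries_data(matrix(rnorm(40), 20, 2))
#' dim(X)
#' @export
timeseries_data <- function(values, region_labels = NULL, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values)) stop("time series must not contain missing values", call. = FALSE)
  n <- nrow(values); p <- ncol(values)
  if (n < 1L || p < 2L)
    stop("need at least 1 observation and 2 regions", call. = FALSE)
  labels <- region_labels %||% colnames(values) %||% paste0("V", seq_len(p))
  if (length(labels) != p)
    stop("`region_labels` must have one entry per column", call. = FALSE)
  colnames(values) <- labels
  if (isTRUE(standardized)) {
    mu <- colMeans(values)
    v <- colMeans(values^2) - mu^2
    if (max(abs(mu)) > 1e-8 || max(abs(v - 1)) > 1e-8)
      stop("`standardized = TRUE` but columns are not mean-0/variance-1", call. = FALSE)
  }
  structure(values, class = c("bggm_timeseries", class(values)),
            standardized = isTRUE(standardized))
}

as_timeseries <- function(X) {
  if (inherits(X, "bggm_timeseries")) return(X)
  timeseries_data(as.matrix(X))
}

#' @export
print.bggm_timeseries <- function(x, ...) {
  cat(sprintf("<bggm_timeseries> %d time points x %d regions%s\n",
              nrow(x), ncol(x),
              if (attr(x, "standardized")) " (standardized)" else ""))
  invisible(x)
}

#' Standardize each region to zero mean and unit variance
#'
#' Columns are centered and scaled using the population variance
#' (\eqn{1/n} denominator) so that the scatter matrix of the result has unit
#' diagonal times \eqn{n}; set `denominator = "n-1"` for the sample variance.
#'
#' @param X A [timeseries_data()] object or numeric matrix.
#' @param denominator Either `"n"` (default, population variance) or `"n-1"`.
#' @return A standardized `bggm_timeseries` object.
#' @examples
#' X <- standardize_timeseries(matrix(rnorm(60, 5, 3), 30, 2))
#' round(colMeans(X), 12)
#' @export
standardize_timeseries <- function(X, denominator = c("n", "n-1")) {
  X <- as_timeseries(X)
  denominator <- match.arg(denominator)
  n <- nrow(X)
  mu <- colMeans(X)
  ctr <- sweep(unclass(X), 2L, mu)
  ss <- colSums(ctr^2)
  bad <- which(ss == 0)
  if (length(bad))
    stop(sprintf("region %s is constant; cannot standardize",
                 paste(colnames(X)[bad], collapse = ", ")), call. = FALSE)
  denom <- if (denominator == "n") n else max(n - 1L, 1L)
  out <- sweep(ctr, 2L, sqrt(ss / denom), "/")
  timeseries_data(out, colnames(X), standardized = (denominator == "n"))
}

#' Scatter matrix of a time series
#'
#' Returns \eqn{\Sigma = X^T X} (unnormalized, no division by \eqn{n})
#' together with the sample count.  This is the sufficient statistic of the
#' zero-mean Gaussian likelihood and the convention used throughout the
#' package: conjugate updates add \eqn{\Sigma} to the prior scale directly.
#'
#' @param X A [timeseries_data()] object or numeric matrix.
#' @return An object of class `bggm_scatter` with fields `sigma` (p x p) and
#'   `n`.
#' @export
scatter_matrix <- function(X) {
  X <- as_timeseries(X)
  sig <- crossprod(unclass(X))
  sig <- 0.5 * (sig + t(sig))
  structure(list(sigma = sig, n = nrow(X), region_labels = colnames(X)),
            class = "bggm_scatter")
}

#' @export
print.bggm_scatter <- function(x, ...) {
  cat(sprintf("<bggm_scatter> p = %d, n = %d\n", nrow(x$sigma), x$n))
  invisible(x)
}

as_scatter <- function(Sigma, n = NULL) {
  if (inherits(Sigma, "bggm_scatter")) return(Sigma)
  check_symmetric(Sigma, "Sigma")
  if (is.null(n)) stop("`n` is required when passing a raw scatter matrix", call. = FALSE)
  structure(list(sigma = Sigma, n = n,
                 region_labels = colnames(Sigma) %||% paste0("V", seq_len(ncol(Sigma)))),
            class = "bggm_scatter")
}

# Cholesky-based positive-definiteness check; errors on failure.
check_pd <- function(K, what = "K") {
  check_symmetric(K, what)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("`%s` is not positive definite", what), call. = FALSE)
  ch
}

#' Zero-mean multivariate Gaussian log likelihood
#'
#' Computes the fully normalized log density of \eqn{n} i.i.d. zero-mean
#' Gaussian observations with precision matrix \eqn{K}:
#' \deqn{\frac{n}{2}\log|K| - \frac12 \langle K, \Sigma\rangle -
#'       \frac{np}{2}\log(2\pi),}
#' where \eqn{\Sigma = X^T X} is the scatter matrix and
#' \eqn{\langle\cdot,\cdot\rangle} the trace inner product.  The
#' \eqn{(2\pi)} constant is included so values are comparable across graphs
#' and usable in marginal-likelihood computations.
#'
#' @param K Positive-definite p x p precision matrix.
#' @param Sigma A [scatter_matrix()] object (or raw matrix plus `n`).
#' @param n Sample count, only needed when `Sigma` is a raw matrix.
#' @return Log-likelihood (scalar).
#' @export
gaussian_log_likelihood <- function(K, Sigma, n = NULL) {
  Sigma <- as_scatter(Sigma, n)
  if (!all(dim(K) == dim(Sigma$sigma)))
    stop("dimensions of `K` and `Sigma` do not match", call. = FALSE)
  ch <- check_pd(K)
  p <- ncol(K)
  logdet <- 2 * sum(log(diag(ch)))
  (Sigma$n / 2) * logdet - 0.5 * sum(K * Sigma$sigma) -
    (Sigma$n * p / 2) * log(2 * pi)
}

#' Transform a precision matrix to partial correlations
#'
#' Applies \eqn{r_{ij} = -k_{ij} / \sqrt{k_{ii} k_{jj}}} off the diagonal and
#' sets \eqn{r_{ii} = 1}.  Zeros of the precision matrix (conditional
#' independencies) map to exactly zero partial correlation, and the transform
#' is invariant to rescaling of \eqn{K}.
#'
#' @param K Symmetric precision matrix with strictly positive diagonal.
#' @return Symmetric partial-correlation matrix with unit diagonal.
#' @examples
#' precision_to_partial(matrix(c(2, 1, 1, 2), 2))
#' @export
precision_to_partial <- function(K) {
  check_symmetric(K, "K")
  d <- diag(K)
  if (any(d <= 0))
    stop("precision matrix has a nonpositive diagonal element", call. = FALSE)
  s <- 1 / sqrt(d)
  R <- -(K * outer(s, s))
  diag(R) <- 1
  dimnames(R) <- dimnames(K)
  R
}
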