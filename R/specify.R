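#' Ambient-noise ("crud") estimate from a correlation matrix
#'
#' Even conceptually unrelated variables correlate at nonzero levels in very
#' large samples; the typical magnitude of such correlations — the ambient
#' noise level, or crud estimate — is a defensible floor for the smallest
#' effect worth calling meaningful when no better basis for a null-region
#' boundary exists.  The estimator is the mean absolute off-diagonal
#' correlation (the strict upper triangle; sign is irrelevant to a symmetric
#' region, and signed means cancel).
#'
#' @param x A square correlation matrix (symmetric, unit diagonal, entries
#'   in `[-1, 1]`, at least 3 variables), or a data frame / matrix of raw
#'   observations (rows = cases) from which the Pearson correlation matrix
#'   is computed.
#' @return An object of class `"ambient_noise"`: list with `mean_abs_r`,
#'   `n_pairs` (`m (m - 1) / 2` for `m` variables), `method`, and
#'   `suggested_delta` (equal to `mean_abs_r`, on the correlation scale).
#'   A zero estimate triggers a warning: a zero-width region degenerates to
#'   the traditional point-null test.
#' @examples
#' m <- matrix(c(1, 0.1, -0.2, 0.1, 1, 0.3, -0.2, 0.3, 1), 3, 3)
#' estimate_ambient_noise(m)   # mean |r| = 0.2
#' @export
estimate_ambient_noise <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop_data("'x' must be a numeric matrix")
  is_corr <- nrow(x) == ncol(x) &&
    all(abs(diag(x) - 1) < 1e-8) &&
    isTRUE(all.equal(x, t(x), tolerance = 1e-8, check.attributes = FALSE))
  if (!is_corr) {
    if (nrow(x) < 4L) stop_data("raw data need at least 4 rows to correlate")
    x <- stats::cor(x)
  }
  m <- ncol(x)
  if (m < 3L) stop_data("a correlation matrix of at least 3 variables is required")
  if (!isTRUE(all.equal(x, t(x), tolerance = 1e-8, check.attributes = FALSE)))
    stop_data("correlation matrix is not symmetric")
  if (any(abs(diag(x) - 1) > 1e-8)) stop_data("correlation matrix diagonal must be 1")
  if (any(x < -1 - 1e-12 | x > 1 + 1e-12))
    stop_data("correlation matrix entries must lie in [-1, 1]")
  off <- x[upper.tri(x)]
  mean_abs <- mean(abs(off))
  if (mean_abs == 0)
    warning("ambient noise estimate is 0: a zero-width null region ",
            "degenerates to the traditional point-null test")
  structure(list(mean_abs_r = mean_abs, n_pairs = m * (m - 1) / 2,
                 method = "mean_abs_offdiagonal", suggested_delta = mean_abs),
            class = "ambient_noise")
}

#' @export
print.ambient_noise <- function(x, ...) {
  cat("Ambient noise (crud) estimate\n")
  cat("  mean |r| over", x$n_pairs, "variable pairs:", signif(x$mean_abs_r, 4), "\n")
  cat("  suggested null-region half-width (correlation scale):",
      signif(x$suggested_delta, 4), "\n")
  invisible(x)
}

#' Read a correlation matrix from CSV
#'
#' Expects a square numeric table with a header row of variable names; an
#' optional leading column of row names is detected and dropped.
#'
#' @param path CSV file path.
#' @return A numeric matrix.
#' @export
read_correlation_matrix <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  # drop a leading row-name column (character labels or a plain 1..m index)
  if (!is.numeric(d[[1]])) {
    rn <- d[[1]]
    d <- d[, -1, drop = FALSE]
    rownames(d) <- rn
  } else if (ncol(d) == nrow(d) + 1L && identical(d[[1]], seq_len(nrow(d)))) {
    d <- d[, -1, drop = FALSE]
  }
  as.matrix(d)
}
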