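#' Construct an effect estimate
#'
#' Bundles an observed effect with its standard error on the analysis scale,
#' the scale label, and optional degrees of freedom and sample-size
#' information.  This is the quantity whose confidence interval is compared
#' against a null region.
#'
#' @param estimate Point estimate on the analysis scale.
#' @param se Standard error on the analysis scale (non-negative).
#' @param scale `"identity"`, `"log"` or `"fisher_z"`.
#' @param df Optional degrees of freedom (> 0) for t-based intervals.
#' @param n_info Optional named list of sample sizes (e.g. `list(n1 = , n2 = )`).
#' @param measure Label: one of `"mean_difference"`, `"proportion_difference"`,
#'   `"correlation"`, `"log_ratio"`, `"raw"`.
#' @return An object of class `"effect_estimate"`.
#' @examples
#' effect_estimate(1.0, 0.5)
#' effect_estimate(log(0.95), 0.03, scale = "log", measure = "log_ratio")
#' @export
effect_estimate <- function(estimate, se, scale = c("identity", "log", "fisher_z"),
                            df = NULL, n_info = NULL,
                            measure = c("raw", "mean_difference",
                                        "proportion_difference", "correlation",
                                        "log_ratio")) {
  scale <- match.arg(scale)
  measure <- match.arg(measure)
  if (!is.numeric(estimate) || length(estimate) != 1L || is.na(estimate))
    stop_spec("'estimate' must be a single number")
  if (!is.numeric(se) || length(se) != 1L || is.na(se) || se < 0)
    stop_spec("'se' must be a single non-negative number")
  if (!is.null(df) && (!is.numeric(df) || length(df) != 1L || is.na(df) || df <= 0))
    stop_spec("'df' must be a single positive number")
  if (measure == "correlation" && scale != "fisher_z")
    stop_spec("a correlation estimate must be on the fisher_z scale")
  structure(list(estimate = estimate, se = se, scale = scale, df = df,
                 n_info = n_info, measure = measure),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("Effect estimate (", x$measure, "): ", signif(x$estimate, 6),
      " (SE ", signif(x$se, 6), ") on the ", x$scale, " scale", sep = "")
  if (!is.null(x$df)) cat(", df =", signif(x$df, 6))
  cat("\n")
  invisible(x)
}

#' Two-sided confidence interval for an effect estimate
#'
#' Computes the symmetric interval `estimate +/- q * se` where `q` is the
#' standard-normal or Student-t quantile at `(1 + level) / 2`.  The interval
#' is computed on the analysis scale; log and Fisher-z intervals are *not*
#' back-transformed here (see [back_transform()]).
#'
#' A two-sided interval at level L used in a one-sided region comparison
#' implies a one-sided test at alpha = (1 - L) / 2; [region_test()] reports
#' this implied alpha.
#'
#' @param est An [effect_estimate()].
#' @param level Confidence level in (0, 1).
#' @param method `"z"`, `"t"`, or `"auto"` (t when `df` is available,
#'   otherwise z).
#' @return An object of class `"conf_interval"`: list with `lower`, `upper`,
#'   `level`, `scale`, `method` and the `estimate` used.
#' @examples
#' compute_ci(effect_estimate(1.0, 0.5), level = 0.95, method = "z")
#' @export
compute_ci <- function(est, level = 0.95, method = c("auto", "z", "t")) {
  stopifnot(inherits(est, "effect_estimate"))
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop_spec("'level' must lie strictly between 0 and 1")
  if (method == "auto") method <- if (!is.null(est$df)) "t" else "z"
  if (method == "t" && is.null(est$df))
    stop_spec("t-method interval requested but the estimate has no df")
  q <- if (method == "z") stats::qnorm((1 + level) / 2)
       else stats::qt((1 + level) / 2, df = est$df)
  hw <- q * est$se
  structure(list(lower = est$estimate - hw, upper = est$estimate + hw,
                 level = level, scale = est$scale, method = method,
                 estimate = est$estimate),
            class = "conf_interval")
}

conf_interval <- function(lower, upper, level, scale = "identity",
                          method = "z", estimate = (lower + upper) / 2) {
  if (lower > upper) stop_spec("interval lower bound exceeds upper bound")
  structure(list(lower = lower, upper = upper, level = level, scale = scale,
                 method = method, estimate = estimate),
            class = "conf_interval")
}

#' @export
print.conf_interval <- function(x, ...) {
  cat(format(100 * x$level), "% CI [", signif(x$lower, 6), ", ",
      signif(x$upper, 6), "] (", x$method, " method, ", x$scale, " scale)\n",
      sep = "")
  invisible(x)
}

#' Effect estimate from two independent groups
#'
#' For `measure = "mean_difference"` the estimate is `mean(y1) - mean(y2)`;
#' the default standard error and degrees of freedom are Welch's (unequal
#' variances), with the pooled-variance t available via `var_equal = TRUE`.
#' For `measure = "proportion_difference"` the outcomes must be binary coded
#' (0/1); the estimate is `p1 - p2` with the Wald standard error and no df
#' (z intervals).
#'
#' @param y1,y2 Numeric outcome vectors, at least 2 observations each.
#' @param measure `"mean_difference"` or `"proportion_difference"`.
#' @param var_equal Use the pooled-variance standard error and
#'   `n1 + n2 - 2` df instead of Welch's (mean difference only).
#' @return An [effect_estimate()].
#' @examples
#' effect_from_two_groups(c(2, 4, 6, 8), c(1, 3, 5, 7))
#' @export
effect_from_two_groups <- function(y1, y2,
                                   measure = c("mean_difference",
                                               "proportion_difference"),
                                   var_equal = FALSE) {
  measure <- match.arg(measure)
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  if (anyNA(y1) || anyNA(y2)) stop_data("missing values in outcome vectors")
  n1 <- length(y1); n2 <- length(y2)
  if (n1 < 2L || n2 < 2L) stop_data("each group needs at least 2 observations")
  if (measure == "mean_difference") {
    v1 <- stats::var(y1); v2 <- stats::var(y2)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      a <- v1 / n1; b <- v2 / n2
      se <- sqrt(a + b)
      df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    }
    effect_estimate(mean(y1) - mean(y2), se, df = df,
                    n_info = list(n1 = n1, n2 = n2),
                    measure = "mean_difference")
  } else {
    if (!all(y1 %in% c(0, 1)) || !all(y2 %in% c(0, 1)))
      stop_data("proportion_difference requires binary (0/1) outcomes")
    p1 <- mean(y1); p2 <- mean(y2)
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    effect_estimate(p1 - p2, se, n_info = list(n1 = n1, n2 = n2),
                    measure = "proportion_difference")
  }
}

#' Correlation effect estimate on the Fisher-z scale
#'
#' Pearson's r transformed by `atanh` with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y Paired numeric vectors, `n >= 4`, each with nonzero variance.
#' @return An [effect_estimate()] on the `fisher_z` scale.
#' @examples
#' set.seed(1)
#' effect_from_correlation(rnorm(30), rnorm(30))
#' @export
effect_from_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_data("x and y must be paired (equal length)")
  if (anyNA(x) || anyNA(y)) stop_data("missing values in x or y")
  n <- length(x)
  if (n < 4L) stop_data("correlation requires at least 4 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_data("zero variance in x or y")
  r <- stats::cor(x, y)
  if (abs(r) >= 1)
    stop_data("degenerate correlation |r| = 1: Fisher z is infinite")
  effect_estimate(atanh(r), 1 / sqrt(n - 3), scale = "fisher_z",
                  n_info = list(n = n), measure = "correlation")
}

#' Back-transform a confidence interval to the natural scale
#'
#' Endpoint-wise inverse transform: `exp` for log-scale intervals, `tanh`
#' for Fisher-z intervals.  Level and ordering are preserved.
#'
#' @param ci A [compute_ci()] result on the log or fisher_z scale.
#' @return A `"conf_interval"` on the natural (identity) scale.
#' @export
back_transform <- function(ci) {
  stopifnot(inherits(ci, "conf_interval"))
  if (ci$scale == "identity") {
    warning("interval is already on the identity scale; returning unchanged")
    return(ci)
  }
  inv <- function(x) from_analysis_scale(x, ci$scale)
  conf_interval(inv(ci$lower), inv(ci$upper), level = ci$level,
                scale = "identity",
                method = paste0(ci$method, "_", ci$scale, "_backed"),
                estimate = inv(ci$estimate))
}

#' Wald or Newcombe interval for a difference of two proportions
#'
#' The Wald interval is the package default because it matches the
#' normal-theory power calculations exactly; the Newcombe hybrid score
#' interval (built from the two Wilson single-proportion intervals) is the
#' better-calibrated alternative for small samples or extreme rates.
#'
#' @param y1,y2 Binary (0/1) outcome vectors.
#' @param level Confidence level in (0, 1).
#' @param method `"wald"` or `"newcombe"` (Wilson-score based).
#' @return A `"conf_interval"`.
#' @export
proportion_difference_ci <- function(y1, y2, level = 0.95,
                                     method = c("wald", "newcombe")) {
  method <- match.arg(method)
  est <- effect_from_two_groups(y1, y2, measure = "proportion_difference")
  if (method == "wald") return(compute_ci(est, level = level, method = "z"))
  wilson <- function(x, n) {
    z <- stats::qnorm((1 + level) / 2)
    ctr <- (x + z^2 / 2) / (n + z^2)
    hw <- z * sqrt(n) / (n + z^2) * sqrt(x / n * (1 - x / n) + z^2 / (4 * n))
    c(ctr - hw, ctr + hw)
  }
  n1 <- length(y1); n2 <- length(y2)
  p1 <- mean(y1); p2 <- mean(y2)
  w1 <- wilson(sum(y1), n1); w2 <- wilson(sum(y2), n2)
  d <- p1 - p2
  conf_interval(d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2),
                d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2),
                level = level, method = "newcombe", estimate = d)
}

#' Read two-group or bivariate data from CSV
#'
#' Long format: one outcome column and one group column (exactly two group
#' levels).  Wide format (for correlations): two numeric columns.  A header
#' row is required.
#'
#' @param path CSV file path.
#' @param outcome_col,group_col Column names for the long format; if
#'   `group_col` is `NULL` the first two numeric columns are returned as a
#'   bivariate data frame.
#' @return For the long format, a list with `y1`, `y2` and the group labels;
#'   for the wide format a two-column data frame.
#' @export
read_effect_data <- function(path, outcome_col = "outcome", group_col = "group") {
  if (!file.exists(path)) stop_data("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(group_col)) {
    num <- d[vapply(d, is.numeric, logical(1))]
    if (ncol(num) < 2L) stop_data("wide format requires two numeric columns")
    return(num[, 1:2])
  }
  if (!all(c(outcome_col, group_col) %in% names(d)))
    stop_data("columns '", outcome_col, "' and '", group_col,
              "' not found in ", path)
  g <- d[[group_col]]
  lv <- unique(g)
  if (length(lv) != 2L) stop_data("group column must have exactly 2 levels, found ",
                                  length(lv))
  list(y1 = d[[outcome_col]][g == lv[1]], y2 = d[[outcome_col]][g == lv[2]],
       groups = as.character(lv))
}
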