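#' Construct an interval of effect values
#'
#' An interval is one contiguous span of population effect values, possibly
#' unbounded on either side, with open or closed finite endpoints.  Intervals
#' are the building blocks of null regions: a null region is the union of one
#' or two disjoint intervals.
#'
#' Infinite endpoints are always open.  A degenerate interval
#' (`lower == upper`) is permitted only when both ends are closed; it
#' represents the point null of the traditional two-sided significance test.
#'
#' @param lower Lower endpoint; may be `-Inf`.
#' @param upper Upper endpoint; may be `Inf`.
#' @param lower_closed,upper_closed Logical; whether the corresponding finite
#'   endpoint belongs to the interval.
#' @return An object of class `"nr_interval"`.
#' @examples
#' interval(-0.2, 0.2)                      # [-0.2, 0.2]
#' interval(-Inf, 0.1)                      # (-Inf, 0.1]
#' interval(0, 0)                           # the point {0}
#' @export
interval <- function(lower, upper, lower_closed = TRUE, upper_closed = TRUE) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L || is.na(lower) || is.na(upper))
    stop_spec("interval endpoints must be single non-missing numbers")
  if (lower > upper)
    stop_spec("interval lower endpoint exceeds upper endpoint")
  if (is.infinite(lower)) lower_closed <- FALSE
  if (is.infinite(upper)) upper_closed <- FALSE
  if (lower == upper && !(lower_closed && upper_closed))
    stop_spec("a degenerate interval must be closed at both ends")
  structure(list(lower = lower, upper = upper,
                 lower_closed = isTRUE(lower_closed),
                 upper_closed = isTRUE(upper_closed)),
            class = "nr_interval")
}

# Membership of a scalar value, honoring open/closed ends.
itv_contains <- function(itv, x) {
  lo_ok <- if (itv$lower_closed) x >= itv$lower else x > itv$lower
  hi_ok <- if (itv$upper_closed) x <= itv$upper else x < itv$upper
  lo_ok & hi_ok
}

# Does the closed interval [l, u] intersect itv?  Vectorized over l, u.
itv_overlaps_closed <- function(itv, l, u) {
  (if (itv$upper_closed) l <= itv$upper else l < itv$upper) &
  (if (itv$lower_closed) u >= itv$lower else u > itv$lower)
}

# Is the closed interval [l, u] wholly contained in itv?  Vectorized.
itv_contains_closed <- function(itv, l, u) {
  (if (itv$lower_closed) l >= itv$lower else l > itv$lower) &
  (if (itv$upper_closed) u <= itv$upper else u < itv$upper)
}

# Is interval a a subset of interval b (as point sets)?
itv_subset <- function(a, b) {
  lo_ok <- b$lower < a$lower ||
    (b$lower == a$lower && (b$lower_closed || !a$lower_closed))
  hi_ok <- b$upper > a$upper ||
    (b$upper == a$upper && (b$upper_closed || !a$upper_closed))
  lo_ok && hi_ok
}

format_itv <- function(itv, digits = 4) {
  lo <- if (is.infinite(itv$lower)) "-Inf" else format(signif(itv$lower, digits))
  hi <- if (is.infinite(itv$upper)) "Inf" else format(signif(itv$upper, digits))
  paste0(if (itv$lower_closed) "[" else "(", lo, ", ", hi,
         if (itv$upper_closed) "]" else ")")
}

#' @export
print.nr_interval <- function(x, ...) {
  cat("Interval", format_itv(x), "\n")
  invisible(x)
}
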