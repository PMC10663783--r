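#' @keywords internal
REGION_KINDS <- c("nhst_two_sided", "nhst_one_sided", "met_one_sided",
                  "met_two_sided", "equivalence", "strong_part1",
                  "strong_part2", "non_inferiority")

SCALES <- c("identity", "log", "fisher_z")

# Natural scale -> analysis scale.
to_analysis_scale <- function(x, scale) {
  switch(scale,
         identity = x,
         log = {
           if (any(x <= 0)) stop_spec("log-scale boundary parameters must be positive ratios")
           log(x)
         },
         fisher_z = {
           if (any(abs(x) >= 1)) stop_spec("fisher_z-scale boundary parameters must lie in (-1, 1)")
           atanh(x)
         },
         stop_spec("unknown scale '", scale, "'"))
}

# Analysis scale -> natural scale.
from_analysis_scale <- function(x, scale) {
  switch(scale, identity = x, log = exp(x), fisher_z = tanh(x),
         stop_spec("unknown scale '", scale, "'"))
}

chk_pos <- function(x, name) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x))
    stop_spec("parameter '", name, "' must be a single number")
  if (x <= 0) stop_spec("parameter '", name, "' must be positive, got ", x)
  x
}

#' Construct the null region of an interval-null test
#'
#' The null region is the set of population effect values that a test seeks
#' to rule out: a test is significant exactly when the confidence interval
#' for the observed effect lies entirely outside it.  Eight geometries are
#' supported, covering the five tests of the unified framework:
#'
#' * `nhst_two_sided` — the point null `{0}` of the traditional two-sided
#'   significance test.
#' * `nhst_one_sided` — `(-Inf, 0]` (benefit direction `"greater"`) or
#'   `[0, Inf)` (`"less"`): effects in the wrong direction or zero.
#' * `met_one_sided` — minimum-effect test: the region extends beyond 0 up to
#'   the weakest effect still considered meaningful, `(-Inf, +delta]`
#'   (direction `"greater"`) or `[-delta, Inf)`.
#' * `met_two_sided` — `[-delta, +delta]`: effects too small to matter in
#'   either direction.
#' * `equivalence` — `(-Inf, -delta] U [+delta, Inf)`: effects large enough
#'   to matter; significance means the effect is practically zero.
#' * `strong_part1` — `[theta - epsilon, theta + epsilon]`: effects close
#'   enough to the theoretically predicted value `theta`; significance means
#'   the theory should be rejected.
#' * `strong_part2` — `(-Inf, theta - epsilon] U [theta + epsilon, Inf)`:
#'   effects too far from `theta`; significance means the theory should be
#'   retained.
#' * `non_inferiority` — the values of unacceptably poor performance of a
#'   new treatment relative to a standard, bounded by the non-inferiority
#'   margin (see Details).
#'
#' @details
#' All finite region boundaries are closed: the boundary values belong to
#' the null hypothesis, so significance requires strict exclusion — the
#' conservative reading of "entirely outside".
#'
#' On `scale = "log"` (ratio measures such as hazard or odds ratios) and
#' `scale = "fisher_z"` (correlations), boundary parameters are supplied on
#' the natural scale and stored after transformation.  Magnitude parameters
#' (`delta`, `epsilon`) must transform to positive half-widths: a log-scale
#' `delta` is a ratio greater than 1, a Fisher-z `delta` is a correlation in
#' (0, 1).  A non-inferiority margin on the log scale is the boundary ratio
#' itself (e.g. a hazard-ratio margin of 1.11 with `direction = "less"`,
#' lower hazard being better, yields the region `[log 1.11, Inf)`); on the
#' identity and Fisher-z scales it is a positive magnitude, placed on the
#' harmful side given by `direction`.
#'
#' Asymmetric minimum-effect and equivalence bounds are available through
#' `delta_lower`/`delta_upper` (both magnitudes; the region spans
#' `[-delta_lower, +delta_upper]` or its complement).
#'
#' @param kind One of the eight geometry names above.
#' @param delta Smallest meaningful effect magnitude (MET, equivalence).
#' @param delta_lower,delta_upper Optional asymmetric bounds replacing
#'   `delta` for `met_two_sided` and `equivalence`.
#' @param theta Theoretically predicted effect (strong-form tests), natural
#'   scale.
#' @param epsilon Half-width of the band of effects "close enough" to
#'   `theta` (strong-form tests).
#' @param ni_margin Non-inferiority margin (see Details).
#' @param direction `"greater"` if larger effects are better (the default),
#'   `"less"` otherwise; meaningful for the one-sided geometries.
#' @param scale Analysis scale: `"identity"`, `"log"` or `"fisher_z"`.
#' @return An object of class `"null_region"`: a list with elements
#'   `intervals` (one or two disjoint [interval()]s, sorted), `geometry`,
#'   `params` (the natural-scale parameters as supplied), `direction` and
#'   `scale`.
#' @examples
#' null_region("met_one_sided", delta = 0.10)          # (-Inf, 0.10]
#' null_region("equivalence", delta = 0.2)             # (-Inf,-0.2] U [0.2,Inf)
#' null_region("strong_part1", theta = 0.75, epsilon = 0.05)  # [0.70, 0.80]
#' # hazard-ratio non-inferiority margin of 1.11, harm = HR above 1:
#' null_region("non_inferiority", ni_margin = 1.11,
#'             direction = "less", scale = "log")
#' @seealso [region_contains()], [region_is_subset()], [region_test()]
#' @export
null_region <- function(kind, delta = NULL, delta_lower = NULL,
                        delta_upper = NULL, theta = NULL, epsilon = NULL,
                        ni_margin = NULL,
                        direction = c("greater", "less"),
                        scale = c("identity", "log", "fisher_z")) {
  if (length(kind) != 1L || !kind %in% REGION_KINDS)
    stop_spec("unknown test geometry '", paste(kind, collapse = ","),
              "'; must be one of: ", paste(REGION_KINDS, collapse = ", "))
  direction <- match.arg(direction)
  scale <- match.arg(scale)

  # A magnitude parameter on the analysis scale: identity requires > 0,
  # log a ratio > 1, fisher_z a correlation in (0, 1).
  halfwidth <- function(x, name) {
    chk_pos(x, name)
    h <- switch(scale, identity = x, log = log(x), fisher_z = {
      if (x >= 1) stop_spec("parameter '", name,
                            "' must be a correlation in (0, 1) on the fisher_z scale")
      atanh(x)
    })
    if (h <= 0)
      stop_spec("parameter '", name, "' must exceed ",
                if (scale == "log") "1 (a ratio)" else "0", " on the ", scale, " scale")
    h
  }

  params <- list()
  ivs <- switch(kind,
    nhst_two_sided = list(interval(0, 0)),
    nhst_one_sided = {
      if (direction == "greater") list(interval(-Inf, 0))
      else list(interval(0, Inf))
    },
    met_one_sided = {
      d <- halfwidth(delta, "delta"); params$delta <- delta
      if (direction == "greater") list(interval(-Inf, d))
      else list(interval(-d, Inf))
    },
    met_two_sided = ,
    equivalence = {
      if (!is.null(delta_lower) || !is.null(delta_upper)) {
        dl <- halfwidth(delta_lower, "delta_lower")
        du <- halfwidth(delta_upper, "delta_upper")
        params$delta_lower <- delta_lower; params$delta_upper <- delta_upper
      } else {
        dl <- du <- halfwidth(delta, "delta")
        params$delta <- delta
      }
      if (kind == "met_two_sided") list(interval(-dl, du))
      else list(interval(-Inf, -dl), interval(du, Inf))
    },
    strong_part1 = ,
    strong_part2 = {
      if (is.null(theta)) stop_spec("strong-form tests require 'theta'")
      th <- to_analysis_scale(theta, scale)
      ep <- halfwidth(epsilon, "epsilon")
      params$theta <- theta; params$epsilon <- epsilon
      if (kind == "strong_part1") list(interval(th - ep, th + ep))
      else list(interval(-Inf, th - ep), interval(th + ep, Inf))
    },
    non_inferiority = {
      chk_pos(ni_margin, "ni_margin")
      params$ni_margin <- ni_margin
      b <- if (scale == "log") {
        if (ni_margin == 1)
          stop_spec("a log-scale non-inferiority margin must differ from 1")
        log(ni_margin)
      } else {
        m <- to_analysis_scale(ni_margin, scale)
        if (m <= 0) stop_spec("ni_margin must be a positive magnitude")
        if (direction == "greater") -m else m
      }
      if (direction == "greater") list(interval(-Inf, b))
      else list(interval(b, Inf))
    })

  structure(list(intervals = ivs, geometry = kind, params = params,
                 direction = direction, scale = scale),
            class = "null_region")
}

#' Test whether a value lies in a null region
#'
#' @param region A [null_region()].
#' @param value Effect value(s) on the region's analysis scale.
#' @return Logical vector: `TRUE` where the value lies in some interval of
#'   the region, honoring open/closed ends.
#' @examples
#' r <- null_region("met_two_sided", delta = 0.2)
#' region_contains(r, c(0, 0.2, 0.3))   # TRUE TRUE FALSE
#' @export
region_contains <- function(region, value) {
  stopifnot(inherits(region, "null_region"))
  out <- rep(FALSE, length(value))
  for (iv in region$intervals) out <- out | itv_contains(iv, value)
  out
}

#' Test whether one null region is a subset of another
#'
#' Point-set containment of `a`'s union of intervals in `b`'s, honoring
#' open/closed ends.  Supports, e.g., the nesting property that the
#' traditional point null is contained in any minimum-effect region.
#'
#' @param a,b [null_region()] objects on the same scale.
#' @return A single logical.
#' @examples
#' region_is_subset(null_region("nhst_two_sided"),
#'                  null_region("met_two_sided", delta = 0.2))   # TRUE
#' @export
region_is_subset <- function(a, b) {
  stopifnot(inherits(a, "null_region"), inherits(b, "null_region"))
  if (a$scale != b$scale)
    stop_spec("regions are on different scales ('", a$scale, "' vs '", b$scale, "')")
  all(vapply(a$intervals, function(ia) {
    any(vapply(b$intervals, function(ib) itv_subset(ia, ib), logical(1)))
  }, logical(1)))
}

geometry_label <- function(kind) {
  switch(kind,
         nhst_two_sided = "two-sided NHST",
         nhst_one_sided = "one-sided NHST",
         met_one_sided = "MET",
         met_two_sided = "MET",
         equivalence = "EqT",
         strong_part1 = "strong-form Part 1",
         strong_part2 = "strong-form Part 2",
         non_inferiority = "non-inferiority testing")
}

# Region rendered on the natural scale for human-facing text.
format_region_natural <- function(region, digits = 4) {
  fmt <- function(iv) {
    tr <- function(x) if (is.infinite(x)) x else from_analysis_scale(x, region$scale)
    format_itv(interval(tr(iv$lower), tr(iv$upper), iv$lower_closed, iv$upper_closed),
               digits)
  }
  paste(vapply(region$intervals, fmt, character(1)), collapse = " U ")
}

#' @export
print.null_region <- function(x, ...) {
  cat("Null region (", geometry_label(x$geometry), ", ", x$geometry, ")\n", sep = "")
  cat("  H0:", paste(vapply(x$intervals, format_itv, character(1)), collapse = " U "),
      "on the", x$scale, "scale\n")
  if (x$scale != "identity")
    cat("  natural scale:", format_region_natural(x), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a null region to JSON
#'
#' Infinite endpoints are written as the string sentinels `"-inf"`/`"inf"`.
#'
#' @param region A [null_region()].
#' @return A JSON string.
#' @seealso [region_from_json()]
#' @export
region_to_json <- function(region) {
  stopifnot(inherits(region, "null_region"))
  num <- function(x) {
    if (is.infinite(x)) {if (x < 0) "-inf" else "inf"} else x
  }
  obj <- list(
    geometry = region$geometry,
    intervals = lapply(region$intervals, function(iv)
      list(lower = num(iv$lower), upper = num(iv$upper),
           lower_closed = iv$lower_closed, upper_closed = iv$upper_closed)),
    scale = region$scale,
    direction = region$direction,
    params = region$params)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Deserialize a null region from JSON
#'
#' @param txt A JSON string produced by [region_to_json()] (or a file path).
#' @return A [null_region()].
#' @export
region_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  num <- function(x) {
    if (identical(x, "inf")) Inf else if (identical(x, "-inf")) -Inf else as.numeric(x)
  }
  ivs <- lapply(obj$intervals, function(iv)
    interval(num(iv$lower), num(iv$upper),
             isTRUE(iv$lower_closed), isTRUE(iv$upper_closed)))
  structure(list(intervals = ivs, geometry = obj$geometry,
                 params = lapply(obj$params, as.numeric),
                 direction = obj$direction %||% "greater",
                 scale = obj$scale),
            class = "null_region")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
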