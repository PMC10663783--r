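# Vectorized three-way classification of closed CIs [l, u] against a region.
classify_ci_vec <- function(l, u, region) {
  overlap <- rep(FALSE, length(l))
  inside <- rep(FALSE, length(l))
  for (iv in region$intervals) {
    overlap <- overlap | itv_overlaps_closed(iv, l, u)
    inside <- inside | itv_contains_closed(iv, l, u)
  }
  out <- rep("overlaps_region", length(l))
  out[inside] <- "inside_region"
  out[!overlap] <- "outside_all"
  out
}

#' Classify a confidence interval against a null region
#'
#' The decision rule of the framework: a test is significant exactly when
#' the confidence interval falls entirely outside the null region(s).  The
#' CI is treated as a closed interval; a CI endpoint exactly equal to a
#' closed region boundary counts as overlap (not exclusion), the strict
#' reading of "entirely outside".
#'
#' @param ci A `"conf_interval"`.
#' @param region A [null_region()] on the same scale.
#' @return One of `"outside_all"` (the CI is disjoint from every null
#'   interval — significant), `"inside_region"` (the CI lies wholly within
#'   the null region), or `"overlaps_region"` (partially in, partially out —
#'   inconclusive).
#' @examples
#' r <- null_region("met_two_sided", delta = 0.2)
#' ci_outside_region(conf_interval_manual(0.3, 0.5, 0.95), r)  # outside_all
#' @export
ci_outside_region <- function(ci, region) {
  stopifnot(inherits(ci, "conf_interval"), inherits(region, "null_region"))
  if (ci$scale != region$scale &&
      !(ci$scale == "identity" && region$scale == "identity"))
    stop_spec("CI is on the '", ci$scale, "' scale but the region is on '",
              region$scale, "'")
  classify_ci_vec(ci$lower, ci$upper, region)
}

#' Construct a confidence interval from explicit bounds
#'
#' For published intervals where only the bounds are reported.
#'
#' @param lower,upper Interval endpoints on the analysis scale.
#' @param level Confidence level in (0, 1).
#' @param scale Analysis scale label.
#' @param method Method label (informational).
#' @export
conf_interval_manual <- function(lower, upper, level = 0.95,
                                 scale = "identity", method = "reported") {
  conf_interval(lower, upper, level = level, scale = scale, method = method)
}

#' Specify an interval-null test
#'
#' A test specification bundles the geometry, its boundary parameters, the
#' confidence level and the CI method, for use by [region_test()],
#' [simulate_oc()] and [required_n()].
#'
#' @inheritParams null_region
#' @param level Confidence level of the (two-sided) CI.
#' @param ci_method `"auto"`, `"z"` or `"t"`.
#' @return An object of class `"test_spec"`.
#' @examples
#' test_spec("met_one_sided", delta = 0.10, level = 0.90)
#' @export
test_spec <- function(kind, delta = NULL, delta_lower = NULL,
                      delta_upper = NULL, theta = NULL, epsilon = NULL,
                      ni_margin = NULL, direction = c("greater", "less"),
                      scale = c("identity", "log", "fisher_z"),
                      level = 0.95, ci_method = c("auto", "z", "t")) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  ci_method <- match.arg(ci_method)
  region <- null_region(kind, delta = delta, delta_lower = delta_lower,
                        delta_upper = delta_upper, theta = theta,
                        epsilon = epsilon, ni_margin = ni_margin,
                        direction = direction, scale = scale)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop_spec("'level' must lie strictly between 0 and 1")
  structure(list(kind = kind, region = region, level = level,
                 ci_method = ci_method, scale = scale),
            class = "test_spec")
}

#' @export
print.test_spec <- function(x, ...) {
  cat("Test spec:", geometry_label(x$kind), "at level", x$level,
      "(", x$ci_method, "CI )\n")
  print(x$region)
  invisible(x)
}

#' Run an interval-null test by the CI-exclusion rule
#'
#' Builds the null region, computes the confidence interval for the
#' estimate, and declares significance exactly when the CI lies entirely
#' outside the region.  The implied one-sided alpha of the two-sided CI,
#' `(1 - level) / 2`, is reported alongside the verdict.
#'
#' `region_test()` is the core entry point; pass either a ready-made
#' [test_spec()] via `spec`, or the geometry and parameters directly.
#'
#' @param est An [effect_estimate()], or a single number (then supply `se`).
#' @param kind Test geometry; see [null_region()].
#' @param spec Optional [test_spec()]; overrides `kind`, parameters, `level`
#'   and `ci_method`.
#' @param se Standard error when `est` is given as a bare number.
#' @param df Degrees of freedom when `est` is given as a bare number.
#' @inheritParams test_spec
#' @return An object of class `"region_test"` with elements `verdict`
#'   (`"significant"` or `"not_significant"`), `position` (see
#'   [ci_outside_region()]), `ci`, `region`, `estimate`, `level`,
#'   `implied_alpha` and `statement`.
#' @examples
#' region_test(1.0, se = 0.5, kind = "nhst_two_sided")
#' region_test(0.05, se = 0.05, kind = "equivalence", delta = 0.2,
#'             level = 0.90)
#' @export
region_test <- function(est, kind = NULL, spec = NULL, se = NULL, df = NULL,
                        delta = NULL, delta_lower = NULL, delta_upper = NULL,
                        theta = NULL, epsilon = NULL, ni_margin = NULL,
                        direction = c("greater", "less"),
                        scale = NULL, level = 0.95,
                        ci_method = c("auto", "z", "t")) {
  if (is.numeric(est)) {
    if (is.null(se)) stop_spec("supply 'se' when 'est' is a bare number")
    est <- effect_estimate(est, se, scale = scale %||% "identity", df = df)
  }
  stopifnot(inherits(est, "effect_estimate"))
  if (is.null(spec)) {
    if (is.null(kind)) stop_spec("supply a test 'kind' or a 'spec'")
    spec <- test_spec(kind, delta = delta, delta_lower = delta_lower,
                      delta_upper = delta_upper, theta = theta,
                      epsilon = epsilon, ni_margin = ni_margin,
                      direction = direction, scale = scale %||% est$scale,
                      level = level, ci_method = match.arg(ci_method))
  }
  stopifnot(inherits(spec, "test_spec"))
  if (spec$scale != est$scale)
    stop_spec("estimate is on the '", est$scale,
              "' scale but the test spec is on '", spec$scale, "'")
  ci <- compute_ci(est, level = spec$level, method = spec$ci_method)
  position <- ci_outside_region(ci, spec$region)
  verdict <- if (position == "outside_all") "significant" else "not_significant"
  res <- structure(list(verdict = verdict, position = position, ci = ci,
                        region = spec$region, estimate = est,
                        level = spec$level,
                        implied_alpha = (1 - spec$level) / 2,
                        statement = NULL),
                   class = "region_test")
  res$statement <- render_statement(res)
  res
}

#' Combine component tests into a composite verdict
#'
#' `met_plus_eqt` combines a minimum-effect test and an equivalence test on
#' the same estimate: the outcome is `meaningful` if MET is significant,
#' `practically_zero` if EqT is significant, and `inconclusive` if neither
#' is (the data do not provide sufficient evidence either way).
#' `strong_form` combines Parts 1 and 2 of the strong-form test:
#' `reject_theory` if Part 1 is significant, `retain_theory` if Part 2 is,
#' `inconclusive` otherwise.
#'
#' With a shared CI and complementary regions the component tests can never
#' both be significant; if both are, the inputs are inconsistent and an
#' error is raised.
#'
#' @param a,b The two component `"region_test"` results (MET + EqT, or
#'   Part 1 + Part 2, in either order).
#' @param kind `"met_plus_eqt"` or `"strong_form"`.
#' @return An object of class `"composite_verdict"`.
#' @export
combined_verdict <- function(a, b, kind = c("met_plus_eqt", "strong_form")) {
  kind <- match.arg(kind)
  stopifnot(inherits(a, "region_test"), inherits(b, "region_test"))
  comps <- list(a, b)
  geoms <- vapply(comps, function(r) r$region$geometry, character(1))
  pick <- function(want) {
    i <- which(geoms %in% want)
    if (length(i) != 1L)
      stop_spec("composite '", kind, "' needs exactly one ",
                paste(want, collapse = "/"), " component")
    comps[[i]]
  }
  if (kind == "met_plus_eqt") {
    met <- pick(c("met_one_sided", "met_two_sided"))
    eqt <- pick("equivalence")
    if (met$verdict == "significant" && eqt$verdict == "significant")
      stop_spec("inconsistent components: MET and EqT cannot both be ",
                "significant with a shared CI and complementary regions")
    outcome <- if (met$verdict == "significant") "meaningful"
               else if (eqt$verdict == "significant") "practically_zero"
               else "inconclusive"
  } else {
    p1 <- pick("strong_part1")
    p2 <- pick("strong_part2")
    if (!isTRUE(all.equal(p1$region$params$theta, p2$region$params$theta)))
      stop_spec("strong-form components must share theta")
    if (p1$verdict == "significant" && p2$verdict == "significant")
      stop_spec("inconsistent components: Parts 1 and 2 cannot both be ",
                "significant with a shared CI and complementary regions")
    outcome <- if (p1$verdict == "significant") "reject_theory"
               else if (p2$verdict == "significant") "retain_theory"
               else "inconclusive"
  }
  res <- structure(list(kind = kind, outcome = outcome, components = comps,
                        statement = NULL),
                   class = "composite_verdict")
  res$statement <- render_statement(res)
  res
}

#' Render a one-line plain-language statement of a result
#'
#' Deterministic template naming the test, the null region (natural scale),
#' the confidence interval and the verdict, e.g. "significant by MET".
#'
#' @param result A `"region_test"` or `"composite_verdict"`.
#' @param ... Unused.
#' @return A character string.
#' @export
render_statement <- function(result, ...) UseMethod("render_statement")

#' @export
render_statement.region_test <- function(result, ...) {
  lab <- geometry_label(result$region$geometry)
  ci <- result$ci
  ci_nat <- if (ci$scale %in% c("log", "fisher_z"))
    suppressWarnings(back_transform(ci)) else ci
  ci_txt <- sprintf("%g%% CI [%s, %s]", 100 * ci$level,
                    format(signif(ci_nat$lower, 4)),
                    format(signif(ci_nat$upper, 4)))
  reg_txt <- format_region_natural(result$region)
  if (result$verdict == "significant") {
    extra <- switch(result$region$geometry,
                    non_inferiority = " the new treatment is non-inferior;",
                    equivalence = " the effect is practically equivalent to zero;",
                    strong_part1 = " the data warrant rejecting the theory;",
                    strong_part2 = " the data warrant retaining the theory;",
                    "")
    sprintf("significant by %s:%s %s lies entirely outside the null region %s.",
            lab, extra, ci_txt, reg_txt)
  } else {
    pos_txt <- if (result$position == "inside_region")
      "lies entirely within" else "partially overlaps"
    sprintf("not significant by %s: %s %s the null region %s.",
            lab, ci_txt, pos_txt, reg_txt)
  }
}

#' @export
render_statement.composite_verdict <- function(result, ...) {
  switch(result$outcome,
         meaningful = "MET significant: the true effect is large enough to be meaningful.",
         practically_zero = "EqT significant: the true effect is close enough to zero to be practically equivalent to it.",
         reject_theory = "Part 1 significant: the true effect is far enough from the predicted value that the theory should be modified or replaced.",
         retain_theory = "Part 2 significant: the true effect is close enough to the predicted value that the theory should be retained.",
         inconclusive = paste("Inconclusive: the data do not provide sufficient",
                              "evidence for either inference; more, and more",
                              "precise, data are needed."))
}

#' @export
print.region_test <- function(x, ...) {
  cat("\n\tInterval-null test by the CI-exclusion rule\n\n")
  cat("Test:    ", geometry_label(x$region$geometry), " (", x$region$geometry,
      ")\n", sep = "")
  cat("H0:      ", paste(vapply(x$region$intervals, format_itv, character(1)),
                         collapse = " U "),
      " on the ", x$region$scale, " scale\n", sep = "")
  cat("Estimate:", signif(x$estimate$estimate, 6), " (SE",
      signif(x$estimate$se, 6), ")\n")
  cat(sprintf("CI:       %g%% [%s, %s]  (%s)\n", 100 * x$level,
              format(signif(x$ci$lower, 6)), format(signif(x$ci$upper, 6)),
              x$ci$method))
  cat("Position: ", x$position, "   implied one-sided alpha: ",
      format(x$implied_alpha), "\n", sep = "")
  cat("Verdict:  ", toupper(x$verdict), "\n\n", sep = "")
  cat(strwrap(x$statement, width = 76), sep = "\n")
  cat("\n")
  invisible(x)
}

#' @export
summary.region_test <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
print.composite_verdict <- function(x, ...) {
  cat("\n\tComposite verdict (", x$kind, "): ", x$outcome, "\n\n", sep = "")
  cat(strwrap(x$statement, width = 76), sep = "\n")
  cat("\nComponents:\n")
  for (r in x$components)
    cat("  - ", r$statement, "\n", sep = "")
  invisible(x)
}

#' Plot a test result: CI against the null region
#'
#' Draws the null region interval(s) as shaded bands and the confidence
#' interval with its point estimate on top, on the analysis scale.
#'
#' @param x A `"region_test"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.region_test <- function(x, ...) {
  fin <- unlist(lapply(x$region$intervals, function(iv)
    c(iv$lower, iv$upper)))
  fin <- fin[is.finite(fin)]
  rng <- range(c(fin, x$ci$lower, x$ci$upper, 0))
  pad <- 0.15 * diff(rng) + 1e-9
  xlim <- c(rng[1] - pad, rng[2] + pad)
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1), yaxt = "n", ylab = "",
                 xlab = paste0("effect (", x$region$scale, " scale)"),
                 main = paste("CI vs null region:",
                              geometry_label(x$region$geometry)), ...)
  for (iv in x$region$intervals)
    graphics::rect(max(iv$lower, xlim[1] - 1), 0.15,
                   min(iv$upper, xlim[2] + 1), 0.85,
                   col = grDevices::adjustcolor("firebrick", 0.25), border = NA)
  graphics::segments(x$ci$lower, 0.5, x$ci$upper, 0.5, lwd = 3)
  graphics::points(x$estimate$estimate, 0.5, pch = 19, cex = 1.3)
  graphics::mtext(x$verdict, side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' The result records verdict, position, region, the CI on both the
#' analysis and (for log / Fisher-z tests) the natural scale, level,
#' implied alpha and the rendered statement.
#'
#' @param result A `"region_test"`.
#' @return A JSON string.
#' @seealso [result_from_json()]
#' @export
result_to_json <- function(result) {
  stopifnot(inherits(result, "region_test"))
  ci_obj <- list(lower = result$ci$lower, upper = result$ci$upper,
                 level = result$ci$level, scale = result$ci$scale,
                 method = result$ci$method, estimate = result$ci$estimate)
  obj <- list(
    verdict = result$verdict,
    position = result$position,
    region = jsonlite::fromJSON(region_to_json(result$region),
                                simplifyVector = FALSE),
    ci = ci_obj,
    level = result$level,
    implied_alpha = result$implied_alpha,
    estimate = list(estimate = result$estimate$estimate,
                    se = result$estimate$se, scale = result$estimate$scale,
                    df = result$estimate$df, measure = result$estimate$measure),
    statement = result$statement)
  if (result$ci$scale %in% c("log", "fisher_z")) {
    nat <- suppressWarnings(back_transform(result$ci))
    obj$ci_natural <- list(lower = nat$lower, upper = nat$upper,
                           level = nat$level, scale = "natural")
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Reconstruct a test result from its JSON serialization
#'
#' Round-trip companion to [result_to_json()]: the reloaded object renders
#' the identical statement.
#'
#' @param txt JSON string (or file path).
#' @return A `"region_test"`.
#' @export
result_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  region <- region_from_json(jsonlite::toJSON(obj$region, auto_unbox = TRUE,
                                              digits = NA))
  est <- effect_estimate(obj$estimate$estimate, obj$estimate$se,
                         scale = obj$estimate$scale,
                         df = obj$estimate$df,
                         measure = obj$estimate$measure %||% "raw")
  ci <- conf_interval(obj$ci$lower, obj$ci$upper, level = obj$ci$level,
                      scale = obj$ci$scale, method = obj$ci$method,
                      estimate = obj$ci$estimate)
  res <- structure(list(verdict = obj$verdict, position = obj$position,
                        ci = ci, region = region, estimate = est,
                        level = obj$level, implied_alpha = obj$implied_alpha,
                        statement = NULL),
                   class = "region_test")
  res$statement <- render_statement(res)
  res
}
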