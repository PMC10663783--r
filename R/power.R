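#' Analytic operating characteristics of an interval-null test
#'
#' Exact rejection, containment and inconclusiveness probabilities under the
#' normal-theory summary model: the estimate is drawn from
#' `Normal(true_effect, se)` and a two-sided z interval at `level` is
#' compared against the region by the CI-exclusion rule.
#'
#' With `q` the standard-normal quantile at `(1 + level) / 2` and `Phi` the
#' normal CDF, the rejection probability is, per region shape:
#' \describe{
#'   \item{single upper-bounded region `(-Inf, b]`}{`Phi((mu - b)/se - q)`}
#'   \item{single lower-bounded region `[b, Inf)`}{`Phi((b - mu)/se - q)`}
#'   \item{bounded region `[a, b]`}{the sum of the two one-sided exclusion
#'     probabilities}
#'   \item{central-gap region `(-Inf, a] U [b, Inf)`}{`max(0,
#'     Phi((b - mu)/se - q) - Phi((a - mu)/se + q))`}
#' }
#' The probability that the CI lies wholly inside the null region follows
#' from the same tail areas, and the inconclusive probability is the
#' remainder.
#'
#' @param region A [null_region()].
#' @param true_effect True effect(s) on the region's analysis scale
#'   (vectorized).
#' @param se Standard error(s) of the estimate, positive (recycled against
#'   `true_effect`).
#' @param level Confidence level of the two-sided CI.
#' @return A data frame with columns `true_effect`, `se`, `p_significant`,
#'   `p_inconclusive`, `p_inside`; one row per input point.
#' @examples
#' r <- null_region("met_one_sided", delta = 0.10)
#' analytic_power(r, true_effect = 0.10, se = 0.1, level = 0.90)  # alpha 0.05
#' @export
analytic_power <- function(region, true_effect, se, level = 0.95) {
  stopifnot(inherits(region, "null_region"))
  if (any(!is.finite(se)) || any(se <= 0))
    stop_spec("'se' must be positive and finite")
  if (level <= 0 || level >= 1)
    stop_spec("'level' must lie strictly between 0 and 1")
  n <- max(length(true_effect), length(se))
  mu <- rep_len(true_effect, n)
  s <- rep_len(se, n)
  q <- stats::qnorm((1 + level) / 2)

  ivs <- region$intervals
  if (length(ivs) == 1L) {
    a <- ivs[[1]]$lower; b <- ivs[[1]]$upper
    if (is.infinite(a) && is.infinite(b))
      stop_spec("degenerate region covering the whole line")
    if (is.infinite(a)) {            # (-Inf, b]
      p_sig <- stats::pnorm((mu - b) / s - q)
      p_in <- stats::pnorm((b - mu) / s - q)
    } else if (is.infinite(b)) {     # [a, Inf)
      p_sig <- stats::pnorm((a - mu) / s - q)
      p_in <- stats::pnorm((mu - a) / s - q)
    } else {                         # [a, b] (possibly the point a == b)
      p_sig <- stats::pnorm((a - mu) / s - q) + stats::pnorm((mu - b) / s - q)
      p_in <- pmax(0, stats::pnorm((b - mu) / s - q) -
                        stats::pnorm((a - mu) / s + q))
    }
  } else {                           # (-Inf, a] U [b, Inf), a < b
    a <- ivs[[1]]$upper; b <- ivs[[2]]$lower
    p_sig <- pmax(0, stats::pnorm((b - mu) / s - q) -
                       stats::pnorm((a - mu) / s + q))
    p_in <- stats::pnorm((a - mu) / s - q) + stats::pnorm((mu - b) / s - q)
  }
  data.frame(true_effect = mu, se = s,
             p_significant = p_sig,
             p_inconclusive = pmax(0, 1 - p_sig - p_in),
             p_inside = p_in)
}

# Normalize a test spec's CI method under a given data model.
resolve_ci_method <- function(spec, has_df) {
  if (spec$ci_method == "auto") {if (has_df) "t" else "z"} else spec$ci_method
}

#' Monte-Carlo operating characteristics over a grid
#'
#' Simulates the test over a grid of true effects and sample sizes, tallying
#' the fraction of replicates that are significant (CI entirely outside the
#' region), inconclusive (CI partially overlapping), or inside the region.
#'
#' Data models:
#' \describe{
#'   \item{`summary_normal`}{the estimate is drawn directly from
#'     `Normal(true_effect, sigma / sqrt(n))` with known standard error
#'     (z intervals).}
#'   \item{`two_group_normal`}{two groups of `n` normal observations with
#'     means differing by `true_effect` and common SD `sigma`; the effect is
#'     estimated by [effect_from_two_groups()] (Welch t intervals by
#'     default).}
#'   \item{`two_group_binomial`}{two groups of `n` Bernoulli outcomes at
#'     rates `baseline + true_effect` and `baseline` (Wald z intervals).}
#' }
#'
#' Reproducibility: each grid cell draws from its own seed stream derived
#' deterministically from the root `seed` and the cell index, so results do
#' not depend on evaluation order and the caller's random state is left
#' untouched.
#'
#' @param spec A [test_spec()].
#' @param true_effect Vector of true effects on the analysis scale.
#' @param n_grid Vector of per-group sample sizes.
#' @param data_model One of `"summary_normal"`, `"two_group_normal"`,
#'   `"two_group_binomial"`.
#' @param reps Replicates per grid cell.
#' @param seed Root seed (integer).
#' @param sigma Observation SD (normal models).
#' @param baseline Control-group event rate (binomial model).
#' @return An object of class `"operating_characteristics"`: list with
#'   `grid` (data frame: `true_effect`, `n`, `se`, `p_significant`,
#'   `p_inconclusive`, `p_inside`), `method`, `reps`, `seed`, `spec`.
#' @examples
#' sp <- test_spec("met_one_sided", delta = 0.1, level = 0.90)
#' simulate_oc(sp, true_effect = c(0.1, 0.3), n_grid = c(25, 100),
#'             reps = 500, seed = 7)
#' @export
simulate_oc <- function(spec, true_effect, n_grid,
                        data_model = c("summary_normal", "two_group_normal",
                                       "two_group_binomial"),
                        reps = 10000, seed = 1, sigma = 1, baseline = 0.5) {
  stopifnot(inherits(spec, "test_spec"))
  data_model <- match.arg(data_model)
  if (!is.numeric(reps) || reps < 1) stop_spec("'reps' must be >= 1")
  if (sigma <= 0) stop_spec("'sigma' must be positive")
  if (data_model == "two_group_binomial") {
    if (baseline <= 0 || baseline >= 1)
      stop_spec("'baseline' rate must lie in (0, 1)")
    bad <- baseline + true_effect
    if (any(bad <= 0 | bad >= 1))
      stop_spec("baseline + true_effect must lie in (0, 1)")
  }
  grid <- expand.grid(true_effect = true_effect, n = n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  q <- stats::qnorm((1 + spec$level) / 2)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$true_effect[i]; n <- grid$n[i]
    rows[[i]] <- with_seed(cell_seed(seed, i), {
      if (data_model == "summary_normal") {
        se <- sigma / sqrt(n)
        x <- stats::rnorm(reps, mu, se)
        l <- x - q * se; u <- x + q * se
        pos <- classify_ci_vec(l, u, spec$region)
        se_rep <- se
      } else if (data_model == "two_group_normal") {
        method <- resolve_ci_method(spec, has_df = TRUE)
        pos <- character(reps); ses <- numeric(reps)
        for (r in seq_len(reps)) {
          y1 <- stats::rnorm(n, mu, sigma); y2 <- stats::rnorm(n, 0, sigma)
          est <- effect_from_two_groups(y1, y2)
          ci <- compute_ci(est, level = spec$level, method = method)
          pos[r] <- classify_ci_vec(ci$lower, ci$upper, spec$region)
          ses[r] <- est$se
        }
        se_rep <- mean(ses)
      } else {
        p1 <- baseline + mu; p2 <- baseline
        x1 <- stats::rbinom(reps, n, p1); x2 <- stats::rbinom(reps, n, p2)
        ph1 <- x1 / n; ph2 <- x2 / n
        d <- ph1 - ph2
        se_vec <- sqrt(ph1 * (1 - ph1) / n + ph2 * (1 - ph2) / n)
        l <- d - q * se_vec; u <- d + q * se_vec
        pos <- classify_ci_vec(l, u, spec$region)
        se_rep <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
      }
      data.frame(true_effect = mu, n = n, se = se_rep,
                 p_significant = mean(pos == "outside_all"),
                 p_inconclusive = mean(pos == "overlaps_region"),
                 p_inside = mean(pos == "inside_region"))
    })
  }
  structure(list(grid = do.call(rbind, rows), method = "monte_carlo",
                 reps = reps, seed = seed, spec = spec,
                 data_model = data_model),
            class = "operating_characteristics")
}

#' Analytic operating characteristics over a grid
#'
#' Convenience wrapper around [analytic_power()] producing the same
#' container as [simulate_oc()] under the summary-normal model with
#' `se = sigma / sqrt(n)`.
#'
#' @inheritParams simulate_oc
#' @return An `"operating_characteristics"` object with `method = "analytic"`.
#' @export
analytic_oc <- function(spec, true_effect, n_grid, sigma = 1) {
  stopifnot(inherits(spec, "test_spec"))
  grid <- expand.grid(true_effect = true_effect, n = n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  se <- sigma / sqrt(grid$n)
  ap <- analytic_power(spec$region, grid$true_effect, se, level = spec$level)
  structure(list(grid = cbind(grid[, c("true_effect", "n")],
                              se = se,
                              ap[, c("p_significant", "p_inconclusive",
                                     "p_inside")]),
                 method = "analytic", spec = spec),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("Operating characteristics (", x$method,
      if (x$method == "monte_carlo")
        paste0(", ", x$reps, " reps, seed ", x$seed), ")\n", sep = "")
  cat("Test:", geometry_label(x$spec$kind), "at level", x$spec$level, "\n")
  print(x$grid, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Power curves against sample size
#'
#' One line of `p_significant` versus `n` per true effect.
#'
#' @param x An `"operating_characteristics"` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.operating_characteristics <- function(x, ...) {
  w <- stats::reshape(x$grid[, c("true_effect", "n", "p_significant")],
                      direction = "wide", idvar = "n",
                      timevar = "true_effect")
  graphics::matplot(w$n, as.matrix(w[, -1, drop = FALSE]), type = "b",
                    pch = 19, lty = 1, log = "x",
                    xlab = "n (per group)", ylab = "P(significant)",
                    ylim = c(0, 1),
                    main = paste("Power:", geometry_label(x$spec$kind)), ...)
  graphics::legend("topleft", bty = "n", lty = 1, pch = 19,
                   col = seq_along(unique(x$grid$true_effect)),
                   legend = paste("true effect",
                                  signif(unique(x$grid$true_effect), 3)))
  invisible(x)
}

#' Smallest sample size attaining a target power
#'
#' Searches for the smallest integer `n` such that the analytic rejection
#' probability under the summary-normal model (`se = sigma / sqrt(n)`)
#' reaches `target_power`, by doubling followed by bisection.  Power at a
#' fixed alternative is non-decreasing in `n` for every region geometry, so
#' the search is exact.
#'
#' For central-gap geometries (equivalence, strong-form Part 2) the
#' attainable power is bounded above when the alternative sits close to a
#' gap edge; if `target_power` is not attainable by `n = max_n` the function
#' returns `NA` with a warning (the documented "unreachable" signal).
#'
#' @param spec A [test_spec()].
#' @param true_effect True effect, strictly inside the alternative
#'   hypothesis (outside the null region).
#' @param sigma Observation-scale SD; `se = sigma / sqrt(n)`.
#' @param target_power Target rejection probability in (0, 1).
#' @param max_n Search cap.
#' @return The smallest such integer `n`, or `NA_integer_` (with a warning)
#'   if the target is unreachable by `max_n`.
#' @examples
#' sp <- test_spec("met_one_sided", delta = 0.10, level = 0.90)
#' required_n(sp, true_effect = 0.25, sigma = 1, target_power = 0.80)
#' @export
required_n <- function(spec, true_effect, sigma, target_power, max_n = 1e7) {
  stopifnot(inherits(spec, "test_spec"))
  if (target_power <= 0 || target_power >= 1)
    stop_spec("'target_power' must lie strictly between 0 and 1")
  chk_pos(sigma, "sigma")
  if (region_contains(spec$region, true_effect))
    stop_spec("power cannot reach target; effect inside null region")
  pw <- function(n) analytic_power(spec$region, true_effect, sigma / sqrt(n),
                                   level = spec$level)$p_significant
  n <- 1
  while (n < max_n && pw(n) < target_power) n <- n * 2
  n <- min(n, max_n)
  if (pw(n) < target_power) {
    warning("target power ", target_power, " unreachable by n = ", max_n,
            " (attained ", signif(pw(n), 4), ")")
    return(NA_integer_)
  }
  lo <- max(1, n %/% 2); hi <- n   # pw(hi) >= target
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}
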