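#' Specify a synthetic-data scenario
#'
#' Scenario specifications drive the seeded synthetic-data generator used
#' throughout the package's tests and simulations: two-group normal
#' outcomes, two-group binary outcomes, or paired bivariate-normal draws
#' with a requested correlation.
#'
#' @param model `"two_group_normal"`, `"two_group_binomial"` or
#'   `"bivariate_normal"`.
#' @param n Per-group (or per-pair) sample size, at least 2.
#' @param seed Integer seed; generation is deterministic given the scenario.
#' @param effect True effect: mean difference (normal model) or risk
#'   difference added to `baseline` (binomial model).
#' @param sd Common observation SD (normal model), positive.
#' @param baseline Control-group event rate in (0, 1) (binomial model).
#' @param correlation True Pearson correlation, `|rho| < 1` (bivariate
#'   model).
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec("two_group_binomial", n = 100, seed = 1,
#'               effect = -0.15, baseline = 0.75)
#' @export
scenario_spec <- function(model = c("two_group_normal", "two_group_binomial",
                                    "bivariate_normal"),
                          n, seed, effect = 0, sd = 1, baseline = 0.5,
                          correlation = 0) {
  model <- match.arg(model)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop_spec("'n' must be a single count >= 2")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_spec("'seed' must be a single integer")
  if (model == "two_group_normal" && sd <= 0)
    stop_spec("'sd' must be positive")
  if (model == "two_group_binomial") {
    rates <- c(baseline, baseline + effect)
    if (any(rates <= 0 | rates >= 1))
      stop_spec("event rates must lie strictly in (0, 1)")
  }
  if (model == "bivariate_normal" && abs(correlation) >= 1)
    stop_spec("'correlation' must satisfy |rho| < 1")
  structure(list(model = model, n = as.integer(n), seed = as.integer(seed),
                 effect = effect, sd = sd, baseline = baseline,
                 correlation = correlation),
            class = "scenario_spec")
}

#' Generate a synthetic dataset from a scenario
#'
#' Deterministic given the scenario's seed; the caller's random state is
#' left untouched.  Two-group models return a long data frame with columns
#' `outcome` and `group` (`"treatment"` receives the effect, `"control"` the
#' reference mean or baseline rate); the bivariate model returns columns
#' `x` and `y`.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame.
#' @examples
#' sp <- scenario_spec("two_group_normal", n = 20, seed = 42, effect = 0.5)
#' head(generate_scenario(sp))
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    switch(spec$model,
      two_group_normal = data.frame(
        outcome = c(stats::rnorm(n, spec$effect, spec$sd),
                    stats::rnorm(n, 0, spec$sd)),
        group = rep(c("treatment", "control"), each = n)),
      two_group_binomial = data.frame(
        outcome = c(stats::rbinom(n, 1, spec$baseline + spec$effect),
                    stats::rbinom(n, 1, spec$baseline)),
        group = rep(c("treatment", "control"), each = n)),
      bivariate_normal = {
        x <- stats::rnorm(n)
        y <- spec$correlation * x +
          sqrt(1 - spec$correlation^2) * stats::rnorm(n)
        data.frame(x = x, y = y)
      })
  })
}

#' Read a scenario specification from YAML or JSON
#'
#' The file must provide `model`, `n` and `seed`; remaining fields default
#' as in [scenario_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario_spec()].
#' @export
scenario_from_file <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  # yaml 1.1 would resolve a bare `n` key to FALSE; keep bool tokens verbatim
  keep_verbatim <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path, handlers = keep_verbatim)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop_usage("scenario file must be .yaml, .yml or .json")
  for (f in c("model", "n", "seed"))
    if (is.null(obj[[f]])) stop_spec("scenario file lacks required field '", f, "'")
  scenario_spec(model = obj$model, n = obj$n, seed = obj$seed,
                effect = obj$effect %||% 0, sd = obj$sd %||% 1,
                baseline = obj$baseline %||% 0.5,
                correlation = obj$correlation %||% 0)
}
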