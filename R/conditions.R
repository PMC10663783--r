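# Condition helpers: every user-facing error in the package is classed so
# callers (and the CLI) can distinguish bad specifications from bad data.

stop_spec <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nullregions_spec_error", "nullregions_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nullregions_data_error", "nullregions_error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nullregions_usage_error", "nullregions_error")))
}

# Run code with a local RNG seed, leaving the caller's random state untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-cell seed stream: cell i of a grid run rooted at `seed`
# always sees the same substream, independent of evaluation order.
cell_seed <- function(seed, i) {
  (as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647
}
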