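# Randomized-case generators shared by the property-style tests.

ALL_KINDS <- c("nhst_two_sided", "nhst_one_sided", "met_one_sided",
               "met_two_sided", "equivalence", "strong_part1",
               "strong_part2", "non_inferiority")

# A random region specification (identity scale) with sane parameters.
random_region_args <- function() {
  kind <- sample(ALL_KINDS, 1)
  args <- list(kind = kind,
               direction = sample(c("greater", "less"), 1))
  if (kind %in% c("met_one_sided", "met_two_sided", "equivalence"))
    args$delta <- runif(1, 0.05, 2)
  if (kind %in% c("strong_part1", "strong_part2")) {
    args$theta <- runif(1, -2, 2)
    args$epsilon <- runif(1, 0.05, 1)
  }
  if (kind == "non_inferiority")
    args$ni_margin <- runif(1, 0.05, 2)
  args
}

random_region <- function() do.call(null_region, random_region_args())

# A point guaranteed to lie inside the region (finite).
point_inside_region <- function(region) {
  iv <- region$intervals[[sample(length(region$intervals), 1)]]
  if (is.finite(iv$lower) && is.finite(iv$upper))
    runif(1, iv$lower, iv$upper)
  else if (is.finite(iv$upper)) iv$upper - rexp(1)
  else iv$lower + rexp(1)
}

# A finite point strictly in the alternative (outside the region), at least
# `gap` away from every boundary.
point_in_alternative <- function(region, gap = 0.2) {
  bounds <- unlist(lapply(region$intervals, function(iv)
    c(iv$lower, iv$upper)))
  for (i in 1:1000) {
    x <- runif(1, -6, 6)
    if (!region_contains(region, x) &&
        all(abs(x - bounds[is.finite(bounds)]) > gap))
      return(x)
  }
  stop("could not find a point in the alternative")
}
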