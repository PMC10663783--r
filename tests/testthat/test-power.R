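test_that("rejection probability at a single-region boundary equals the implied alpha", {
  for (se in c(0.01, 0.1, 1, 10)) {
    r <- null_region("met_one_sided", delta = 0.10)
    p <- analytic_power(r, true_effect = 0.10, se = se, level = 0.90)
    expect_equal(p$p_significant, 0.05, tolerance = 1e-12)
  }
  # lower-bounded region: same by symmetry
  r <- null_region("non_inferiority", ni_margin = 0.3, direction = "less")
  p <- analytic_power(r, true_effect = 0.3, se = 0.5, level = 0.90)
  expect_equal(p$p_significant, 0.05, tolerance = 1e-12)
})

test_that("power approaches 1 deep in the alternative as the SE shrinks", {
  r <- null_region("met_one_sided", delta = 0.10)
  p <- analytic_power(r, true_effect = 0.5, se = c(0.2, 0.05, 0.01, 0.001),
                      level = 0.95)
  # non-decreasing throughout; strictly increasing before saturating at 1
  expect_true(all(diff(p$p_significant) >= 0))
  expect_lt(p$p_significant[1], p$p_significant[2])
  expect_gt(p$p_significant[4], 1 - 1e-12)
})

test_that("the probability triple sums to one and stays in [0, 1]", {
  set.seed(71)
  for (i in 1:50) {
    r <- random_region()
    p <- analytic_power(r, runif(5, -3, 3), runif(1, 0.01, 2),
                        level = runif(1, 0.5, 0.99))
    tot <- p$p_significant + p$p_inconclusive + p$p_inside
    expect_true(all(abs(tot - 1) < 1e-9))
    expect_true(all(p$p_significant >= 0 & p$p_significant <= 1))
    expect_true(all(p$p_inside >= 0 & p$p_inside <= 1))
  }
  expect_error(analytic_power(random_region(), 0, se = 0),
               class = "nullregions_spec_error")
})

test_that("analytic power matches a Monte-Carlo oracle at a reference point", {
  r <- null_region("met_one_sided", delta = 0.10)
  p <- analytic_power(r, true_effect = 0.20, se = 0.05, level = 0.90)$p_significant
  # independent brute-force oracle: direct draws and the raw CI rule
  set.seed(72)
  reps <- 100000
  x <- rnorm(reps, 0.20, 0.05)
  q <- qnorm(0.95)
  emp <- mean(x - q * 0.05 > 0.10)
  expect_lt(abs(p - emp), 3 * sqrt(emp * (1 - emp) / reps))
})

test_that("type-I error is capped over the whole null region", {
  set.seed(73)
  level <- 0.90
  alpha <- (1 - level) / 2
  # The degenerate point null is a special case: its CI-exclusion test is the
  # usual two-sided test, whose size is 1 - level = 2 * implied alpha, with
  # the supremum at the point itself.
  pt <- null_region("nhst_two_sided")
  expect_equal(analytic_power(pt, 0, se = 0.05, level = level)$p_significant,
               1 - level, tolerance = 1e-9)
  regions <- list(
    null_region("nhst_one_sided"),
    null_region("met_one_sided", delta = 0.5),
    null_region("met_two_sided", delta = 0.5),
    null_region("equivalence", delta = 0.5),
    null_region("strong_part1", theta = 1, epsilon = 0.5),
    null_region("strong_part2", theta = 1, epsilon = 0.5),
    null_region("non_inferiority", ni_margin = 0.5))
  for (r in regions) {
    pts <- unique(c(vapply(r$intervals, function(iv) {
      c(if (is.finite(iv$lower)) iv$lower else iv$upper - 3,
        if (is.finite(iv$upper)) iv$upper else iv$lower + 3)
    }, numeric(2))))
    pts <- c(pts, vapply(seq_len(20), function(i) point_inside_region(r),
                         numeric(1)))
    p <- analytic_power(r, pts, se = 0.05, level = level)
    expect_true(all(p$p_significant <= alpha + 1e-9))
    # the supremum is attained at a finite boundary
    fin <- unlist(lapply(r$intervals, function(iv)
      c(iv$lower, iv$upper)))
    fin <- fin[is.finite(fin)]
    pb <- analytic_power(r, fin, se = 0.05, level = level)
    expect_equal(max(pb$p_significant), alpha, tolerance = 1e-6)
  }
})

test_that("analytic power is non-decreasing in n for alternatives, all geometries", {
  set.seed(74)
  specs <- list(
    list(r = null_region("nhst_two_sided"), mu = 0.3),
    list(r = null_region("met_one_sided", delta = 0.1), mu = 0.35),
    list(r = null_region("met_two_sided", delta = 0.1), mu = -0.4),
    list(r = null_region("equivalence", delta = 0.4), mu = 0.05),
    list(r = null_region("strong_part1", theta = 0.75, epsilon = 0.05), mu = 0.6),
    list(r = null_region("strong_part2", theta = 0.75, epsilon = 0.2), mu = 0.78),
    list(r = null_region("non_inferiority", ni_margin = 0.2), mu = 0.1))
  ns <- round(10^seq(0.5, 4, length.out = 12))
  for (s in specs) {
    p <- analytic_power(s$r, s$mu, 1 / sqrt(ns), level = 0.9)$p_significant
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("NHST power diverges to 1 while MET power vanishes for a trivial effect", {
  # the contrast motivating interval nulls: a tiny nonzero true effect
  mu <- 0.05
  ns <- c(1e2, 1e3, 1e4, 1e5)
  nhst <- analytic_power(null_region("nhst_two_sided"), mu, 1 / sqrt(ns),
                         level = 0.95)$p_significant
  met <- analytic_power(null_region("met_one_sided", delta = 0.1), mu,
                        1 / sqrt(ns), level = 0.95)$p_significant
  expect_true(all(diff(nhst) > 0))
  expect_gt(nhst[4], 0.99)
  expect_lt(met[4], 1e-6)
  expect_true(all(diff(met) < 0))
})

test_that("inconclusiveness vanishes as precision grows, off the boundary", {
  for (mu in c(0.02, 0.3)) {        # inside the belt, and in the alternative
    r <- null_region("met_two_sided", delta = 0.1)
    p <- analytic_power(r, mu, se = 1 / sqrt(c(1e2, 1e4, 1e6)), level = 0.9)
    expect_true(all(diff(p$p_inconclusive) <= 1e-12))
    expect_lt(p$p_inconclusive[3], 1e-6)
  }
})

test_that("Monte-Carlo grids are reproducible, order-independent, and valid", {
  sp <- test_spec("equivalence", delta = 0.3, level = 0.90)
  oc1 <- simulate_oc(sp, true_effect = c(0, 0.2), n_grid = c(20, 80),
                     reps = 2000, seed = 99)
  oc2 <- simulate_oc(sp, true_effect = c(0, 0.2), n_grid = c(20, 80),
                     reps = 2000, seed = 99)
  expect_identical(oc1$grid, oc2$grid)
  tot <- with(oc1$grid, p_significant + p_inconclusive + p_inside)
  expect_true(all(tot == 1))
  # a single replicate gives degenerate frequencies
  oc3 <- simulate_oc(sp, 0.1, 50, reps = 1, seed = 1)
  expect_true(all(unlist(oc3$grid[, 4:6]) %in% c(0, 1)))
})

test_that("raw-data Monte-Carlo models recover the analytic summary behavior", {
  sp <- test_spec("met_one_sided", delta = 0.2, level = 0.90)
  # two-group normal: power near the large-sample analytic value
  oc <- simulate_oc(sp, true_effect = 0.6, n_grid = 60,
                    data_model = "two_group_normal", reps = 800, seed = 5,
                    sigma = 1)
  ana <- analytic_power(sp$region, 0.6, sqrt(2 / 60), level = 0.90)$p_significant
  expect_lt(abs(oc$grid$p_significant - ana),
            4 * sqrt(ana * (1 - ana) / 800) + 0.02)
  # two-group binomial under the null: capped type-I error
  spb <- test_spec("met_one_sided", delta = 0.2, level = 0.90)
  ocb <- simulate_oc(spb, true_effect = 0, n_grid = 200,
                     data_model = "two_group_binomial", reps = 2000,
                     seed = 6, baseline = 0.5)
  expect_lt(ocb$grid$p_significant, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("required_n matches an exhaustive scan and flags unreachable targets", {
  sp <- test_spec("met_one_sided", delta = 0.10, level = 0.90)
  n_star <- required_n(sp, true_effect = 0.25, sigma = 1, target_power = 0.80)
  # brute-force oracle: scan every n
  pw <- analytic_power(sp$region, 0.25, 1 / sqrt(1:5000), level = 0.90)$p_significant
  expect_equal(n_star, min(which(pw >= 0.80)))

  # boundary effect: power equals alpha for every n, so any higher target fails
  expect_error(required_n(sp, true_effect = 0.10, sigma = 1,
                          target_power = 0.2),
               class = "nullregions_spec_error")  # 0.10 is inside H0
  # narrow equivalence gap: attainable power is bounded below the target
  spe <- test_spec("equivalence", delta = 0.1, level = 0.90)
  expect_warning(n_u <- required_n(spe, true_effect = 0.099, sigma = 1,
                                   target_power = 0.9, max_n = 1e5),
                 "unreachable")
  expect_true(is.na(n_u))

  # monotonicity: farther from the boundary needs fewer observations
  ns <- vapply(c(0.15, 0.2, 0.3, 0.5), function(mu)
    required_n(sp, mu, sigma = 1, target_power = 0.8), integer(1))
  expect_true(all(diff(ns) < 0))
})
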