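test_that("CI position against a region follows the exclusion rule", {
  met <- null_region("met_two_sided", delta = 0.2)
  expect_equal(ci_outside_region(conf_interval_manual(0.3, 0.5, 0.95), met),
               "outside_all")
  # a CI even partially within the null region is not excluded
  expect_equal(ci_outside_region(conf_interval_manual(0.1, 0.5, 0.95), met),
               "overlaps_region")
  expect_equal(ci_outside_region(conf_interval_manual(-0.1, 0.1, 0.95), met),
               "inside_region")
  # touching a closed boundary counts as overlap, not exclusion
  expect_equal(ci_outside_region(conf_interval_manual(0.2, 0.4, 0.95), met),
               "overlaps_region")

  eq <- null_region("equivalence", delta = 0.2)
  expect_equal(ci_outside_region(conf_interval_manual(-0.1, 0.1, 0.95), eq),
               "outside_all")
  expect_equal(ci_outside_region(conf_interval_manual(0.25, 0.5, 0.95), eq),
               "inside_region")
  expect_equal(ci_outside_region(conf_interval_manual(0.1, 0.25, 0.95), eq),
               "overlaps_region")

  expect_error(
    ci_outside_region(conf_interval_manual(0, 1, 0.95, scale = "log"), met),
    class = "nullregions_spec_error")
})

test_that("the two-sided point-null test matches its CI", {
  res <- region_test(1.0, se = 0.5, kind = "nhst_two_sided", level = 0.95,
                     ci_method = "z")
  expect_equal(res$verdict, "significant")        # 0 outside [0.02, 1.98]
  expect_equal(res$implied_alpha, 0.025)
  res2 <- region_test(0.9, se = 0.5, kind = "nhst_two_sided", level = 0.95,
                      ci_method = "z")
  expect_equal(res2$verdict, "not_significant")   # CI now covers 0
})

test_that("non-inferiority verdict from a published hazard-ratio CI", {
  # margin HR = 1.11; reported CI [0.85, 1.05] sits entirely below it
  est <- effect_estimate(log(sqrt(0.85 * 1.05)),
                         (log(1.05) - log(0.85)) / (2 * qnorm(0.975)),
                         scale = "log", measure = "log_ratio")
  res <- region_test(est, kind = "non_inferiority", ni_margin = 1.11,
                     direction = "less", scale = "log", level = 0.95)
  nat <- back_transform(res$ci)
  expect_equal(c(nat$lower, nat$upper), c(0.85, 1.05))
  expect_equal(res$verdict, "significant")
  expect_match(res$statement, "non-inferior")
})

test_that("an estimate inside the region is never significant, at any precision", {
  # regardless of sample size: the CI always contains the estimate
  set.seed(61)
  for (i in 1:100) {
    args <- random_region_args()
    level <- sample(c(0.8, 0.9, 0.95, 0.99), 1)
    sp <- do.call(test_spec, c(args, list(level = level, ci_method = "z")))
    x <- point_inside_region(sp$region)
    se <- runif(1, 1e-8, 10)
    res <- region_test(effect_estimate(x, se), spec = sp)
    expect_equal(res$verdict, "not_significant")
  }
  # and in the zero-se limit
  r <- null_region("met_one_sided", delta = 0.1)
  sp <- test_spec("met_one_sided", delta = 0.1, level = 0.95)
  res0 <- region_test(effect_estimate(0.05, 0), spec = sp)
  expect_equal(res0$verdict, "not_significant")
})

test_that("MET significance implies point-null significance but not conversely", {
  set.seed(62)
  for (i in 1:50) {
    est <- effect_estimate(runif(1, -3, 3), runif(1, 0.01, 1))
    level <- sample(c(0.9, 0.95), 1)
    delta <- runif(1, 0.05, 1)
    met <- region_test(est, kind = "met_two_sided", delta = delta,
                       level = level, ci_method = "z")
    nhst <- region_test(est, kind = "nhst_two_sided", level = level,
                        ci_method = "z")
    if (met$verdict == "significant")
      expect_equal(nhst$verdict, "significant")
  }
  # explicit converse counterexample: CI excludes 0 but not the MET belt
  est <- effect_estimate(0.15, 0.05)
  expect_equal(region_test(est, kind = "nhst_two_sided", ci_method = "z")$verdict,
               "significant")
  expect_equal(region_test(est, kind = "met_two_sided", delta = 0.2,
                           ci_method = "z")$verdict,
               "not_significant")
})

test_that("composite MET + EqT verdicts cover the three outcomes", {
  sp_met <- function(est) region_test(est, kind = "met_two_sided", delta = 0.2,
                                      level = 0.9, ci_method = "z")
  sp_eqt <- function(est) region_test(est, kind = "equivalence", delta = 0.2,
                                      level = 0.9, ci_method = "z")
  big <- effect_estimate(0.8, 0.1)
  tiny <- effect_estimate(0.01, 0.05)
  vague <- effect_estimate(0.2, 0.5)

  v <- combined_verdict(sp_met(big), sp_eqt(big))
  expect_equal(v$outcome, "meaningful")
  v <- combined_verdict(sp_eqt(tiny), sp_met(tiny))   # order-free
  expect_equal(v$outcome, "practically_zero")
  v <- combined_verdict(sp_met(vague), sp_eqt(vague))
  expect_equal(v$outcome, "inconclusive")
  expect_match(v$statement, "do not provide sufficient evidence")
})

test_that("strong-form composite maps Part 1/2 significance to theory verdicts", {
  t1 <- function(est) region_test(est, kind = "strong_part1", theta = 0.75,
                                  epsilon = 0.05, level = 0.9, ci_method = "z")
  t2 <- function(est) region_test(est, kind = "strong_part2", theta = 0.75,
                                  epsilon = 0.05, level = 0.9, ci_method = "z")
  far <- effect_estimate(0.60, 0.02)     # well below the predicted band
  close <- effect_estimate(0.75, 0.01)
  vague <- effect_estimate(0.70, 0.05)

  expect_equal(combined_verdict(t1(far), t2(far), "strong_form")$outcome,
               "reject_theory")
  expect_equal(combined_verdict(t1(close), t2(close), "strong_form")$outcome,
               "retain_theory")
  expect_equal(combined_verdict(t1(vague), t2(vague), "strong_form")$outcome,
               "inconclusive")
  # mismatched theta is rejected
  bad <- region_test(close, kind = "strong_part2", theta = 0.8, epsilon = 0.05,
                     level = 0.9, ci_method = "z")
  expect_error(combined_verdict(t1(close), bad, "strong_form"),
               class = "nullregions_spec_error")
})

test_that("Parts 1 and 2 with equal epsilon and a shared CI are never both significant", {
  set.seed(63)
  for (i in 1:200) {
    theta <- runif(1, -2, 2); eps <- runif(1, 0.02, 1)
    est <- effect_estimate(runif(1, theta - 3, theta + 3), runif(1, 0.005, 2))
    level <- sample(c(0.8, 0.9, 0.95, 0.99), 1)
    r1 <- region_test(est, kind = "strong_part1", theta = theta, epsilon = eps,
                      level = level, ci_method = "z")
    r2 <- region_test(est, kind = "strong_part2", theta = theta, epsilon = eps,
                      level = level, ci_method = "z")
    expect_false(r1$verdict == "significant" && r2$verdict == "significant")
  }
})

test_that("statements name the test and the verdict", {
  met <- region_test(0.8, se = 0.1, kind = "met_two_sided", delta = 0.2)
  expect_match(met$statement, "significant by MET")
  eqt <- region_test(0.01, se = 0.03, kind = "equivalence", delta = 0.2,
                     level = 0.9)
  expect_match(eqt$statement, "significant by EqT")
  expect_match(eqt$statement, "practically equivalent to zero")
})

test_that("identical inputs yield identical results", {
  a <- region_test(0.31, se = 0.07, kind = "met_one_sided", delta = 0.1,
                   level = 0.9)
  b <- region_test(0.31, se = 0.07, kind = "met_one_sided", delta = 0.1,
                   level = 0.9)
  expect_identical(a, b)
})

test_that("results round-trip through JSON, reproducing the statement", {
  set.seed(64)
  cases <- list(
    region_test(0.8, se = 0.1, kind = "met_two_sided", delta = 0.2),
    region_test(0.01, se = 0.03, kind = "equivalence", delta = 0.2, level = 0.9),
    region_test(effect_estimate(log(0.95), 0.03, scale = "log"),
                kind = "non_inferiority", ni_margin = 1.11,
                direction = "less", scale = "log"))
  for (res in cases) {
    txt <- result_to_json(res)
    res2 <- result_from_json(txt)
    expect_equal(res2$verdict, res$verdict)
    expect_equal(res2$position, res$position)
    expect_identical(render_statement(res2), res$statement)
  }
})
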