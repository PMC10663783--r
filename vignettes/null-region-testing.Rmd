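---
title: "Interval-null testing by the CI-exclusion rule: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-null testing by the CI-exclusion rule: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullregions)
```

## The model

Traditional significance testing rules out a single population value — no
effect at all. Most scientific questions are not about that point: they ask
whether an effect is *large enough to matter*, *small enough to ignore*,
*close enough to a theoretical prediction*, or *not unacceptably worse* than
a standard. Each of those questions corresponds to a **null region**: a set
of population effect values the test seeks to rule out, consisting of one or
two contiguous intervals. All the tests in this package share one decision
rule:

> A test is **significant** exactly when the confidence interval for the
> observed effect lies *entirely outside* the null region(s).

The geometries (`null_region()`):

| test | H0 region | significance means |
|---|---|---|
| `nhst_two_sided` | `{0}` | some effect exists |
| `nhst_one_sided` | `(-Inf, 0]` | effect in the right direction |
| `met_one_sided` | `(-Inf, +delta]` | effect exceeds the smallest meaningful size |
| `met_two_sided` | `[-delta, +delta]` | effect meaningful in either direction |
| `equivalence` | `(-Inf, -delta] U [+delta, Inf)` | effect practically zero |
| `strong_part1` | `[theta-eps, theta+eps]` | reject the theory predicting `theta` |
| `strong_part2` | `(-Inf, theta-eps] U [theta+eps, Inf)` | retain the theory |
| `non_inferiority` | the harmful side of the margin | new treatment non-inferior |

`region_test()` applies the rule to an `effect_estimate()` and returns a
classed result with a three-way position: `outside_all` (significant),
`inside_region` (the estimate itself is in H0; no sample size can rescue
it), or `overlaps_region` (inconclusive — the data cannot distinguish the
hypotheses). The three-way classification exists because the composite
verdicts need it: `combined_verdict()` reports `meaningful` /
`practically_zero` / `inconclusive` for a MET + EqT pair and
`reject_theory` / `retain_theory` / `inconclusive` for a strong-form pair.

## Parameters that matter

* `delta` — the smallest effect worth caring about (MET and equivalence),
  on the natural scale of the effect: a difference in means or proportions
  on the identity scale, a ratio greater than 1 on the log scale, a
  correlation in (0, 1) on the Fisher-z scale. There is no default: it is a
  scientific judgment. When no literature basis exists,
  `estimate_ambient_noise()` offers a floor — the mean absolute off-diagonal
  correlation of a large correlation matrix, i.e. the typical magnitude of
  correlations between conceptually unrelated variables. We use the mean of
  |r| rather than a signed or Fisher-z-averaged mean because sign is
  irrelevant to a symmetric region and signed means cancel.
* `theta`, `epsilon` — the predicted value and the tolerance band of the
  strong-form tests. Parts 1 and 2 may in principle use different epsilons;
  the default is equal, and the mutual-exclusivity guarantee (Parts 1 and 2
  never both significant on a shared CI) is only asserted for the equal
  case.
* `ni_margin` — the non-inferiority margin. On the log scale it is the
  boundary ratio itself (e.g. a hazard-ratio margin of 1.11 with
  `direction = "less"` because lower hazard is better); on the identity and
  Fisher-z scales it is a positive magnitude placed on the harmful side.
* `level` — the confidence level of the two-sided CI; a choice that trades
  power against false positives. A two-sided CI at level L used against a
  single-interval region acts as a one-sided test at the **implied alpha**
  `(1 - L)/2`, which every result reports: a 95% CI gives one-sided tests at
  0.025, a 90% CI at 0.05. The same `(1 - L)/2` is the implied TOST alpha of
  the equivalence test.
* `ci_method` — `"z"` or `"t"`; the default `"auto"` uses t whenever degrees
  of freedom are available (Welch df for two-group mean differences) and z
  otherwise (proportion differences, Fisher-z correlations, summary input).

## Direction and scale conventions

Effects are oriented "greater = better/stronger" by default; a `direction`
flag flips the one-sided geometries. Ratio effects (hazard, odds) are
analyzed on the log scale and correlations on the Fisher-z scale; users
supply natural-scale boundaries, the package stores and compares everything
on the analysis scale, and `back_transform()` returns natural-scale
intervals for reporting. Hazard ratios enter only as (estimate, SE) summary
input on the log scale — the package does not fit survival models.

## Numerical and boundary choices

* **Closedness.** All finite region boundaries are closed — the boundary
  belongs to H0 — and the CI is treated as a closed interval, so a CI
  endpoint exactly on a boundary counts as overlap, not exclusion. This is
  the conservative reading of "entirely outside". For continuous sampling
  models the choice has probability zero of mattering; it fixes the
  deterministic edge cases.
* **Degenerate inputs.** A zero SE yields the degenerate CI `[x, x]`, which
  behaves correctly under the rule (an estimate inside the region remains
  non-significant at infinite precision). A correlation of |r| = 1 is
  rejected (infinite Fisher z), as are groups smaller than 2 and zero
  variance inputs.
* **`required_n()` search.** Doubling then bisection on the analytic power,
  which is non-decreasing in n at any fixed alternative, so the search is
  exact; the cap (default `1e7`) makes the unreachable case well-defined —
  `NA` with a warning. Unreachability arises when the target exceeds the
  attainable power by the cap, e.g. an equivalence alternative sitting very
  close to the gap edge.
* **Seeding.** Every Monte-Carlo routine takes one root seed; each grid cell
  draws from a substream derived deterministically from the root seed and
  the cell index (`seed + 104729 * i mod 2^31 - 1`), so a grid is
  reproducible independent of evaluation order, and the caller's RNG state
  is always restored.

## Operating characteristics

Under the summary-normal model — estimate ~ Normal(true effect,
`sigma/sqrt(n)`), z intervals — rejection probabilities have closed forms
from normal tail areas (`analytic_power()`). With `q` the normal quantile at
`(1+level)/2` and `Phi` the normal CDF:

* region `(-Inf, b]`: `P = Phi((mu - b)/se - q)`;
* region `[b, Inf)`: `P = Phi((b - mu)/se - q)`;
* bounded region `[a, b]`: the sum of the two one-sided exclusions;
* central gap `(a, b)` (equivalence, strong Part 2):
  `P = max(0, Phi((b - mu)/se - q) - Phi((a - mu)/se + q))`.

Two properties follow and are verified in the test suite:

* **Type-I capping.** For every interval-null geometry the rejection
  probability over H0 is maximized at a finite boundary, where it equals the
  implied alpha (plus a far-side term that is negligible whenever the region
  is wider than a few SEs). Chance alone can therefore produce a
  "significant" result at most at rate alpha, however small the sample. The
  degenerate point null is the exception worth knowing: its CI-exclusion
  test is the ordinary two-sided test, whose size is `1 - level`, i.e. twice
  the implied one-sided alpha.
* **The sample-size contrast.** For a true effect that is nonzero but inside
  a minimum-effect region, point-null NHST power climbs to 1 as n grows
  while MET power falls to 0 — precision helps rather than hurts
  falsification. Conversely, an *observed* effect inside the region is never
  significant at any n, because its CI always contains it. Growing n also
  drives the probability of an inconclusive (overlapping) outcome to zero
  whenever the true effect is off the boundary.

`simulate_oc()` estimates the same quantities by brute-force simulation,
either from the summary-normal model or from raw two-group normal/binomial
data routed through the same estimation code users run
(`effect_from_two_groups()`), and is the package's independent check on the
closed forms. A calibration note: a Monte-Carlo cell with true rejection
probability p has binomial noise `sqrt(p(1-p)/reps)`, so when many cells are
compared against the analytic values at a fixed per-cell multiple of that
SE, a handful of chance exceedances just past 3 SEs is the expected behavior
of a *correct* implementation (about 0.3% of cells), and near-zero-power
cells cannot be resolved below one count (`1/reps`). The test suite runs
these grids at 20,000 replicates per cell with fixed seeds; problem sizes
throughout the suite (grids of 5 effects × 5 sample sizes, 10,000–50,000
replicates for single-point checks, 1,000-dataset cross-validation against
TOST) were chosen to make binomial noise small relative to the quantities
compared.

## The synthetic-data generator

`scenario_spec()` / `generate_scenario()` produce the only data the package
ever needs: two-group normal outcomes (equal SD, effect = mean difference),
two-group binary outcomes (baseline rate plus a risk difference), and
bivariate normal pairs with a requested correlation. These emulate the
clean, independent, correctly-specified sampling situations the operating
characteristics are derived under. They deliberately do **not** emulate
unequal variances beyond what Welch estimation absorbs, non-normal tails,
clustered or paired designs, missingness, measurement error, or selection —
so passing tests demonstrate the decision rule, the geometry and the power
machinery, not robustness of the inference to real-world data pathologies.
The equivalence verdict is cross-validated against the classical two
one-sided t-tests procedure on 1,000 generated datasets; with matched
Welch-t intervals the two routes agree exactly, which is the known
CI-vs-TOST equivalence rather than an empirical discovery.

## Design choices made where the design was open

* Only symmetric two-sided CIs are produced; one-sided tests consume them
  and report the implied one-sided alpha rather than constructing one-sided
  intervals.
* Wald proportion SEs are the default so the binomial simulations match the
  normal-theory power formulas; the Newcombe hybrid score interval
  (`proportion_difference_ci(method = "newcombe")`) is the better small-sample
  choice but is not the default.
* When MET and EqT are run jointly, both are run at the user's level with no
  multiplicity adjustment, and both results are reported; the geometry makes
  simultaneous significance impossible, but the joint error rate over the
  two questions is not controlled beyond that.
* Asymmetric MET/equivalence bounds (`delta_lower`/`delta_upper`) are
  supported; the symmetric form is the default and the documented norm.
* `simulate_oc()` with raw-data models uses the same t/z interval the user
  would get from `region_test()`, so simulated operating characteristics
  include the small t-vs-z difference rather than idealizing it away.

## Known limitations

* The analytic power model assumes a normal estimate with known SE; t-based
  small-sample operating characteristics are available only by simulation.
* No survival-model fitting, regression adjustment, clustered SEs, or
  correlation/HR sampling models beyond the summary-normal approximation.
* Null regions with more than two intervals (and Bayesian ROPE-style
  machinery) are out of scope.
* The ambient-noise estimator reports the correlation-scale crud magnitude;
  converting it to other effect measures is left to the user, and no
  reference value is asserted — the magnitude is an open empirical question
  and discipline-specific.
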