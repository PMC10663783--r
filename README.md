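# nullregions

Interval-null hypothesis tests via the confidence-interval exclusion rule.

## The problem

Traditional null hypothesis significance testing (NHST) can only rule out a
single population value — exactly zero effect. That is rarely the question a
scientist, a trialist or a replication team actually has: they want to know
whether an effect is **large enough to matter** (minimum-effect testing,
MET), **small enough to be practically zero** (equivalence testing, EqT),
**close to or far from a theoretically predicted value** (strong-form
testing, Parts 1 and 2), or **not unacceptably worse than a standard
treatment** (non-inferiority testing). Each of these tests states its null
hypothesis as a *region* of population values, and every one of them —
including ordinary one- and two-sided NHST — reduces to a single decision
rule:

> the test is significant exactly when the confidence interval for the
> observed effect lies **entirely outside** the prespecified null region(s).

`nullregions` implements that unified framework for biostatistical and
behavioural research: region construction for all the test geometries (on
the identity, log-ratio and Fisher-z correlation scales), effect estimation
from summary statistics or raw two-group / bivariate data, the decision rule
with three-way outcomes (significant / inconclusive / estimate-inside-H0),
composite MET+EqT and strong-form verdicts, exact and Monte-Carlo operating
characteristics (type-I error, power, inconclusiveness), sample-size search,
and an ambient-noise ("crud") estimator for choosing region boundaries when
no better basis exists.

Writing the region as `[a, b]` and the level-L confidence interval as
`[l, u]`, the core machinery is: significance iff `u < a` or `l > b` (for
every H0 interval); under a normal summary model the rejection probability
against `(-Inf, b]` is `Phi((mu - b)/se - q)` with `q` the normal quantile
at `(1+L)/2`, which caps the type-I error at the implied one-sided alpha
`(1 - L)/2` everywhere in H0 — chance alone cannot produce significance at
more than that rate, at any sample size, and an observed effect inside the
region can never be significant at all.

## Worked example

A two-arm study with a binary outcome: the control arm responds at 75%, and
we call a difference of at least 10 percentage points meaningful
(`delta = 0.10`). With 400 patients per arm:

```r
library(nullregions)

d <- generate_scenario(scenario_spec("two_group_binomial", n = 400, seed = 11,
                                     effect = -0.15, baseline = 0.75))
y1 <- d$outcome[d$group == "treatment"]; y2 <- d$outcome[d$group == "control"]
est <- effect_from_two_groups(y1, y2, measure = "proportion_difference")
est
#> Effect estimate (proportion_difference): -0.13 (SE 0.0324514) on the identity scale

met <- region_test(est, kind = "met_two_sided", delta = 0.10, level = 0.90)
eqt <- region_test(est, kind = "equivalence",   delta = 0.10, level = 0.90)
met
#>
#> 	Interval-null test by the CI-exclusion rule
#>
#> Test:    MET (met_two_sided)
#> H0:      [-0.1, 0.1] on the identity scale
#> Estimate: -0.13  (SE 0.0324514 )
#> CI:       90% [-0.183378, -0.0766222]  (z)
#> Position: overlaps_region   implied one-sided alpha: 0.05
#> Verdict:  NOT_SIGNIFICANT

combined_verdict(met, eqt)
#>
#> 	Composite verdict (met_plus_eqt): inconclusive
#>
#> Inconclusive: the data do not provide sufficient evidence for either
#> inference; more, and more precise, data are needed.
```

The observed drop of 13 points is *nominally* beyond the 10-point boundary,
but its 90% CI `[-0.183, -0.077]` still overlaps the null region
`[-0.1, 0.1]`: neither "meaningful" nor "practically zero" is warranted —
the honest verdict is *inconclusive*, and the implied one-sided alpha of
0.05 tells you what error rate the 90% CI buys. With 2000 per arm the same
pipeline gives CI `[-0.206, -0.158]`, entirely outside the region, and the
composite verdict becomes `meaningful` ("significant by MET").

Planning works the same way. How many observations (per the summary-normal
model, `se = sigma/sqrt(n)`) to detect a true effect of 0.25 against a
one-sided MET boundary of 0.10 with 80% power?

```r
sp <- test_spec("met_one_sided", delta = 0.10, level = 0.90)
required_n(sp, true_effect = 0.25, sigma = 1, target_power = 0.80)
#> [1] 275
analytic_power(sp$region, true_effect = 0.10, se = 0.1, level = 0.90)
#>   true_effect  se p_significant p_inconclusive p_inside
#> 1         0.1 0.1          0.05            0.9     0.05
```

At the boundary itself the rejection probability is exactly the implied
alpha, 0.05 — the type-I cap.

A command-line wrapper over the same functions is installed at
`system.file("cli", "nullregions.R", package = "nullregions")`, with
subcommands `test`, `power`, `samplesize`, `simulate-data` and
`ambient-noise`; machine-readable JSON/CSV goes to stdout or `--out`,
human-readable statements to stderr.

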