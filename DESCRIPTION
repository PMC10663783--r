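Package: nullregions
Title: Interval-Null Hypothesis Tests via the Confidence-Interval Exclusion Rule
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A unified framework for interval-null hypothesis testing in
    which one-sided and two-sided null hypothesis significance tests,
    minimum-effect tests, equivalence tests, strong-form (theory
    corroboration) tests and non-inferiority tests all reduce to a single
    decision rule: is the confidence interval entirely outside the
    prespecified null region(s)?  Provides constructors for null regions on
    the identity, log and Fisher-z scales, effect estimation from summary
    statistics or raw two-group and bivariate data, analytic and Monte-Carlo
    operating characteristics (type-I error, power, inconclusiveness),
    sample-size search, an ambient-noise ("crud") estimator for choosing
    region boundaries, a seeded synthetic-data generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
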