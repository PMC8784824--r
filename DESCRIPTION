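Package: mrcount
Title: Mendelian Randomization for Count and Rate Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Instrumental-variable analysis of count outcomes observed over
    varying person-time, built around a quasi-Poisson second stage. Provides
    weighted genetic risk score construction with allele orientation and
    instrument-strength diagnostics (F, partial R-squared, conditional
    Sanderson-Windmeijer F), one-sample Wald-ratio estimation with
    delta-method standard errors, multivariable one-sample MR with bootstrap
    intervals, a two-sample summary-statistics estimator suite (exact-weights
    IVW, MR-Egger, penalized weighted median, weighted mode, multivariable
    IVW) with Cochran and Ruecker heterogeneity statistics and leave-one-out
    screening, conventional quasi-Poisson rate regressions with multiple
    imputation and Rubin pooling, and a calibrated synthetic cohort generator
    emulating a large biobank with overdispersed admission counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
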