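Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for pharmacovigilance signal detection
    in spontaneous reporting databases. Reads FAERS-style quarterly ASCII
    tables and VigiAccess-style aggregate counts, applies latest-version
    deduplication and primary-suspect filtering, builds drug-event 2x2
    contingency tables at the preferred-term and system-organ-class levels,
    and computes four disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with chi-squared, the Bayesian confidence
    propagation neural network information component, and the multi-item
    gamma-Poisson shrinker empirical-Bayes geometric mean) with a joint
    four-method signal criterion and cross-database signal intersection.
    Includes Weibull time-to-onset modelling with failure-type
    classification, Kaplan-Meier cumulative incidence, stratified
    sensitivity analyses, and a synthetic spontaneous-report generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
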