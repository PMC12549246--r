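Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Modelling
    for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pharmacovigilance analysis of FAERS-style
    spontaneous adverse-event report data: ingestion of quarterly ASCII
    tables, FDA-rule deduplication by case identifier, primary-suspect
    cohort selection with MedDRA preferred-term to system-organ-class
    mapping, four-method disproportionality signal detection (reporting
    odds ratio, proportional reporting ratio with chi-squared, Bayesian
    confidence propagation neural network information component, and
    multi-item gamma Poisson shrinker empirical Bayes geometric mean),
    Weibull time-to-onset modelling, sex and age stratified signal
    re-estimation, and outcome-severity tabulation.  A synthetic
    report generator with known ground truth makes the whole pipeline
    testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
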