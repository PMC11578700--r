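Package: faersig
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse event reports: ingestion of quarterly
    ASCII tables, FDA-rule case deduplication, cohort construction against a
    drug dictionary and Standardized MedDRA Query (SMQ) term sets,
    four-algorithm disproportionality analysis (reporting odds ratio,
    proportional reporting ratio with Pearson chi-squared, Bayesian
    confidence propagation neural network information component, and
    multi-item gamma Poisson shrinker empirical Bayes geometric mean),
    Kaplan-Meier time-to-onset analysis with log-rank comparisons, and
    hospitalization/mortality contrasts. Includes a synthetic FAERS-like
    data generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
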