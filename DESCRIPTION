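Package: pneumotrace
Title: Rule-Based EHR Identification, Grading and Costing of
    Treatment-Related Pneumonitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies cases of immune-checkpoint-inhibitor (ICI) and
    radiotherapy pneumonitis from free-text CT thorax reports with a
    two-stage keyword cascade, structured treatment filters and temporal
    episode deduplication; attributes each episode to ICI and/or
    radiotherapy with configurable look-back windows; grades severity on
    CTCAE v5.0 from structured clinical flags and quantifies dual-rater
    concordance with Krippendorff's alpha; extracts 16-week healthcare
    resource utilisation profiles and compares severity strata with
    Welch's t-test; and prices symptomatic cases with a weighted
    unit-cost model built on NHS reference costs.  A synthetic EHR
    generator with ground-truth labels makes every pipeline stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
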