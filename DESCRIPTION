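Package: qocprofile
Title: Facility Performance Profiling for HIV Quality-of-Care Indicators
Version: 0.1.0
Authors@R:
    person("QoC", "Profiling Team", email = "qocprofile@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the performance of health facilities on
    HIV care-and-treatment quality indicators computed from patient-level
    electronic medical record (EMR) extracts. Implements six indicators
    (test-and-start timeliness, viral-load monitoring, multi-month
    scripting appropriateness, timely ART pick-up, and 6-month ART
    retention for pregnant and non-pregnant adults), indirect
    standardization (case-mix adjustment) of the continuity-of-care
    indicators via logistic regression, exact binomial and
    normal-approximation hypothesis tests per facility with
    Bonferroni-corrected outlier flagging, multiplicative (winsorized
    phi) and additive (method-of-moments tau-squared) over-dispersion
    handling, funnel-plot target and control-limit computation, and a
    capped, relevance-weighted, correlation-adjusted composite
    performance z-score. Includes a synthetic EMR generator with known
    ground truth (facility effects, case-mix confounding, planted
    outliers) so the whole pipeline is testable without access to
    governed patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    withr
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
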