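Package: hipscreen
Title: Cost-Effectiveness of Densitometry and CT-Based Finite-Element
    Screening Pathways for Hip Fracture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare areal bone mineral density (DXA-aBMD) and
    CT-based subject-specific finite-element (QCT-SSFE) femoral strength as
    hip-fracture risk predictors, and to weigh the health-economic case for
    switching between them.  Generates seeded, pair-matched case-control
    cohorts calibrated to target discrimination (AUC) and prediction-error
    (%SEE, %SER) levels; computes regression-based error metrics, rank AUC
    and threshold classification accuracy; runs three screening/treatment
    triage pathways (T-score, femoral-strength, and a dual triage that
    resolves the osteopenic band with a strength test) with 10-year
    assessment, treatment and fracture-care costs; derives fractures
    avoided, QALYs gained and incremental cost-effectiveness ratios; and
    performs clinical-trial sample-size/cost comparisons plus a radiation
    risk-benefit calculation for the extra CT dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
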