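Package: nutcast
Title: Now-Casting Acute Malnutrition Burden in Crisis Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts stratum-month prevalence of acute malnutrition among
    children 6-59 months old in crisis-affected settings. Provides a full
    pipeline from child-level anthropometric survey reanalysis (LMS z-score
    conversion, flagging and exclusion, SAM/GAM case definitions, survey
    quality and sampling-coverage weighting, design-based prevalence with
    cluster-robust uncertainty) and stratum-month predictor-panel engineering
    (missingness screening, interpolation, market-weighted and
    chained-equation imputation, per-population rates, rolling means, spline
    smoothing, lag-window features) through weighted quasi-binomial and
    gaussian generalised linear models with all-subsets search, holdout
    shortlisting and leave-one-survey-out cross-validation, and random-forest
    regression with jackknife prediction intervals, to a formula-defined
    performance evaluation suite (mean square error, relative bias, relative
    precision, effective coverage and threshold sensitivity/specificity).
    Includes a seeded synthetic-data generator with known ground truth so the
    whole pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    MASS,
    sandwich,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
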