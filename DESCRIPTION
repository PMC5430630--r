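Package: homarg
Title: Homoarginine and Cardiometabolic Outcomes: Observational and
    Mendelian-Randomization Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying serum L-homoarginine
    (hArg) and cardiometabolic health in cohort and summary-statistics data.
    Provides rule-based phenotyping of prevalent and incident outcomes
    (harmonized metabolic-syndrome components, obesity, high insulin, type 2
    diabetes, coronary artery calcification, high-risk carotid measures),
    sex-stratified metabolome-wide association scanning with a principal
    component based effective-number-of-tests correction, bidirectional
    stepwise-AIC determinant modelling, incident-outcome logistic models, and
    a two-sample summary-level Mendelian randomization engine (Wald ratios,
    first-order-weight inverse-variance weighting, multiplicative random
    effects, Cochran's Q heterogeneity, instrument F-statistics). Includes
    calibrated synthetic-data generators so every stage is testable without
    access to individual-level cohort data or consortium summary files.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
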