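Package: picniccval
Title: External Validation and Recalibration of the PICNICC Febrile
    Neutropenia Risk Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to externally validate the PICNICC (Predicting Infectious
    ComplicatioNs In Children with Cancer) logistic prediction model for
    microbiologically documented infection in paediatric febrile neutropenia.
    Scores episode-level data with the published model, computes per-study
    discrimination (C-statistic) and calibration (E/O ratio, calibration slope
    and intercept) with bootstrap uncertainty, pools performance across studies
    by random-effects meta-analysis with REML estimation, prediction intervals
    and meta-regression, summarises clinical utility at a risk threshold by
    bivariate sensitivity-specificity meta-analysis, implements four intercept
    and slope recalibration strategies, and generates synthetic multi-study
    cohorts with configurable miscalibration for pipeline checks.
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
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
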