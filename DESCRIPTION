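Package: prescore
Title: Parameter Response Efficacy Scores for Predicting Long-Term Drug
    Effects from Short-Term Risk-Marker Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a drug's long-term relative risk reduction on kidney
    and cardiovascular composite outcomes from its short-term effects on
    routine risk markers (HbA1c, systolic blood pressure, urinary
    albumin-creatinine ratio, body weight, hemoglobin, HDL and LDL
    cholesterol, serum potassium).  Marker-outcome associations are
    estimated with a multivariable Cox proportional hazards model on an
    independent background cohort and transferred onto the baseline and
    follow-up marker values of a two-arm trial; the placebo-adjusted change
    in mean predicted risk is the Parameter Response Efficacy (PRE) score.
    Includes parametric-bootstrap confidence intervals, chained-equation
    imputation with predictive mean matching for missing follow-up
    measurements, responder-enrichment simulation for trial design, and a
    synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
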