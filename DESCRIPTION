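Package: lnrads
Title: LN-RADS Ultrasound Lymph-Node Risk Stratification and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, configurable rule engine assigning LN-RADS
    categories (1, 2, 3, 4a, 4b, 5) to superficial lymph nodes from
    ultrasound morphometrics, subjective grades, architectural findings and
    clinical context, together with the evaluation toolkit used to validate
    such a system against histopathology: per-category confusion summaries,
    diagnostic accuracy with Wilson confidence intervals, category-wise
    malignancy risk, cohort-stratified sensitivity, per-feature ROC analysis
    with Youden-index cutoffs and DeLong intervals, and Cohen's kappa
    inter-rater agreement. A seeded synthetic-cohort generator emulating the
    published per-cohort feature distributions makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    optparse,
    jsonlite
Config/testthat/edition: 3
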