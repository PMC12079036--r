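Package: smileval
Title: Smile-Event Classification from Facial Blendshape Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify smile events in short facial action-unit
    blendshape recordings and to validate the machine classification against
    a human rater panel. Provides readers and writers for per-frame blendshape
    CSV data, a bilateral OR-threshold classifier over left/right blendshape
    pairs (AU6 cheek raiser, AU12 lip corner puller), fixed-grid ROC analysis
    with Youden-optimal threshold selection and trapezoidal AUC,
    participant- and class-stratified train/test splitting, multi-rater
    consensus labelling with Fleiss' kappa, confusion-matrix metrics with
    Cohen's kappa (asymptotic confidence interval and test), and a seeded
    synthetic-data generator that emulates the statistical structure of a
    smile-annotation study so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
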