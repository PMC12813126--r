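Package: vcgmi
Title: Myocardial Infarction Detection from Vectorcardiographic Loop Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for three-lead (Frank) vectorcardiographic
    recordings aimed at automated detection of myocardial infarction.
    Provides reading of WFDB and CSV records, long-window Savitzky-Golay
    baseline-wander removal, R-peak detection and QRS/T loop segmentation,
    twelve morphological loop features (optimal-plane arc length and area,
    maximum loop vectors, centroid distance, tracing-velocity statistics),
    nonparametric feature screening, a 210-configuration classifier grid
    evaluated under stratified 10-fold cross-validation, and a stacking
    meta-classifier trained on out-of-fold predictions, together with a
    synthetic cohort generator with analytic ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    rpart,
    randomForest,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
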