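Package: metricomp
Title: Evaluation Metrics and Statistical Tests for Supervised Machine
    Learning Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the evaluation metrics commonly used for supervised
    machine learning tasks in medical imaging and beyond (binary,
    multi-class and multi-label classification, regression, image
    segmentation, object detection and ranked retrieval) directly from
    their defining formulas, and provides the paired statistical tests
    used to compare models (sign, Wilcoxon signed-rank, Friedman with the
    Iman-Davenport correction, McNemar, DeLong, and variance tests), a
    rule-based advisor that selects a suitable test for a given evaluation
    scenario, cross-validation fold planning, and seeded synthetic-data
    generators for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    RNifti,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
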