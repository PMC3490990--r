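Package: docsvm
Title: Jointly Calibrated and Discriminative Linear Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear classifiers for clinical risk prediction that jointly
    optimize discrimination and probability calibration by minimizing a
    combination of the hinge loss and the squared (ridge regression) loss,
    together with the measurement theory connecting the two goals: the
    Mann-Whitney and trapezoidal formulations of the area under the ROC
    curve, the two-component Brier score decomposition into dis-calibration
    and refinement, Hosmer-Lemeshow goodness-of-fit tests with equal-width
    and equal-count binning, reliability diagrams, bounds linking refinement
    and hinge loss to the AUC, Platt scaling, a DeLong z-test for paired
    AUCs, cross-validated hyperparameter selection, and seeded synthetic
    data generators that reproduce the calibration-discrimination tradeoff.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
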