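Package: embryoscreen
Title: Morphodynamic Feature Screening and Miscarriage-Risk Prediction for
    Time-Lapse Embryo Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting first-trimester miscarriage risk of
    positively implanted IVF embryos from time-lapse imaging. Implements a
    314-feature morphodynamic catalog (static morphology, morphokinetic event
    times with all pairwise intervals, ratios and distance-from-linear-
    regression statistics, and pronucleus dynamics extracted by Lucas-Kanade
    optical-flow tracking), a Kolmogorov-Smirnov / Kullback-Leibler feature
    screening cascade with Monte-Carlo cross-validated tree-ensemble scoring,
    backward and two-step forward wrapper selection, random-forest and
    gradient-boosted ensemble predictors with SHAP-based explanation, and a
    synthetic cohort and zygote-movie generator with ground truth so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
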