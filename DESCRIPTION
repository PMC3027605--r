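Package: acghMet
Title: Copy-Number Aberration Analysis for Metastasis-Site Prediction from
    Array CGH
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for predicting the site of colorectal-cancer
    metastasis from array-CGH copy-number profiles of the primary tumor.
    Implements recurrent-aberration detection on kernel-smoothed aggregate
    log2-ratio profiles with a randomization null (KC-SMART style),
    differential-aberration detection between patient groups by a
    per-grid-point signal-to-noise statistic with permutation-estimated
    false discovery rates, a nearest shrunken centroids classifier for
    metastasis site with cross-validation and ROC evaluation, regional
    copy-number summaries with logistic-regression odds ratios, and a
    synthetic aCGH cohort generator with planted aberrations for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
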