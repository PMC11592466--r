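Package: wmcmtex
Title: Wavelet Multi-Sub-Band Co-Occurrence Texture Features and Ensemble
    Classification for Histopathology Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Texture-based relapse prediction for histopathology image tiles.
    Provides blank-tile filtering and contrast-limited adaptive histogram
    equalization (CLAHE), single-level 2D wavelet-packet decomposition with
    per-sub-band gray-level co-occurrence matrices summed into a wavelet
    multi-sub-band co-occurrence matrix (WMCM), eleven co-occurrence texture
    statistics, SMOTE minority oversampling, six base classifiers combined by
    weighted averaging, soft voting and hard voting, the standard binary
    classification metrics with ROC/AUC, and an integer confusion-matrix
    inference utility for auditing published metric tables. A seeded
    synthetic-texture generator makes the whole pipeline testable without
    external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
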