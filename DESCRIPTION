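Package: milpath
Title: Attention-Based Multiple Instance Learning for Slide-Level
    Treatment-Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised prediction of pathologic complete response
    (pCR) to neoadjuvant chemotherapy from pre-treatment H&E biopsy slides.
    Slides are tiled into non-overlapping patches, patches are encoded to
    feature vectors through a pluggable encoder interface, and a tanh
    attention mechanism aggregates patch features into a slide embedding
    classified by a sigmoid head trained with a class-weighted binary
    cross-entropy loss. Includes patient-stratified k-fold evaluation with
    the standard panel of classification metrics, attention-heatmap
    post-processing (median and top-k% hotspot masks, pixel-level
    binarization), coverage-style overlap scoring of attention masks
    against binary biomarker masks, and a synthetic-data generator with
    planted signal patches for end-to-end testing without any slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
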