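Package: usnerveseg
Title: Median-Nerve Ultrasound Segmentation with Synthetic Speckle Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for automated median-nerve
    segmentation in ultrasound-like images: synthetic speckle-phantom
    generation with known nerve geometry and a simulated human rater,
    tracing-to-mask preprocessing with crop/pad geometry, intensity-based
    augmentation (CLAHE, gamma correction, multiplicative speckle noise), a
    4-level encoder-decoder convolutional segmentation network trained with
    Adam on categorical cross-entropy, pixel-overlap evaluation metrics
    (Dice, IoU, accuracy, precision, specificity, sensitivity), and
    cross-sectional-area agreement statistics (paired differences, Pearson
    correlation with Fisher-z intervals, ICC(2,1), Bland-Altman limits of
    agreement). Experiment drivers orchestrate baseline, cross-dataset
    generalization, and repeated-split designs over phantom datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
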