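Package: agmrunet
Title: Attention-Gated MultiRes U-Net for Breast Ultrasound Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, audits and trains an attention-gated multi-resolution
    residual U-Net for binary lesion segmentation in B-mode breast ultrasound
    images. The encoder-decoder graph is declarative, so layer shapes and
    parameter counts can be inspected and diffed against a reference layer
    table. Includes a self-contained speckle phantom generator producing
    BUSI-style image/mask PNG trees, paired geometric augmentation, the full
    confusion-matrix metric suite (accuracy, sensitivity, specificity,
    precision, F1, Dice, rank-based AUC) with k-fold aggregation, a binary
    cross-entropy/Adam training loop with reduce-on-plateau scheduling, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
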