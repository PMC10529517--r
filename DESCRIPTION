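Package: hypercam
Title: Weakly Supervised Fracture Localization with HyperColumn Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a multi-resolution attention-fused convolutional classifier
    on radiographs labelled only as fracture or non-fracture, and localizes the
    fracture by thresholding gradient-weighted class activation (Grad-CAM)
    heatmaps into predicted bounding boxes. Implements channel and spatial
    attention gating (CBAM), hypercolumn feature stacking across network
    depths, CLAHE multi-channel preprocessing with Otsu bone cropping, mix-up
    and geometric augmentation, the Lion optimizer with weighted cross-entropy
    and Smooth L1 coordinate regression, and an evaluation suite (accuracy,
    precision, recall, F1, Cohen's kappa, ROC/AUC, intersection-over-union).
    Includes a synthetic radiograph phantom generator with known fracture
    boxes so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
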