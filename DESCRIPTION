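Package: hemoseg
Title: Residual U-Net Segmentation of Intracranial Hemorrhage on CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for binary segmentation of intracranial
    hemorrhage (ICH) on axial CT slices: phantom CT cohort generation for
    testing, NIfTI scan/mask ingestion with per-slice extraction and mask
    binarization, class-conditional mask-consistent data augmentation
    (flips, brightness, small rotations), a residual U-Net with iterative
    deep feature aggregation trained with Adam on a combined binary
    cross-entropy and Dice loss, k-fold cross-validated training, and a
    full detection/segmentation metric suite (IOU, precision, recall, F1,
    accuracy, specificity, object-level detection at an IOU threshold,
    fold-wise ROC with mean AUC, and demographic subgroup reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rlang,
    RNifti,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
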