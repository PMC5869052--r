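Package: voxpipe
Title: Patch-Based Deep Learning Pipelines for Volumetric Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular pipeline for patch-based deep learning on volumetric
    medical images: dataset discovery and NIfTI loading with spatial metadata,
    intensity normalization (mean/variance and trained histogram-landmark
    standardization), random affine spatial augmentation, window samplers
    (uniform, weighted, grid, resize) with matching whole-volume aggregators,
    composable named-scope network blocks (dense feature stacks, a small
    V-shaped reference segmentation network) trained by reverse-mode automatic
    differentiation with soft Dice, RMSE and adversarial losses, a
    configuration-driven train/inference/evaluation driver with reproducible
    checkpointing, and a full 3D segmentation evaluation suite (overlap,
    volume, surface-distance and region-wise metrics). Synthetic multi-organ
    phantom generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
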