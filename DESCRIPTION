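Package: unifocal
Title: Unified Focal Losses and Evaluation Tools for Class-Imbalanced
    Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the hierarchy of distribution-based (cross entropy,
    Focal), region-based (Dice, Tversky, Focal Tversky) and compound (Combo,
    Hybrid Focal, Unified Focal) loss functions used for semantic
    segmentation under severe foreground/background class imbalance,
    together with their analytic gradients, hard evaluation metrics (Dice,
    IoU, recall, precision), a seeded generator of class-imbalanced
    synthetic segmentation tasks, and a desk-scale benchmark harness built
    around a small fully-convolutional segmenter trained on the CPU. The
    symmetric and asymmetric Unified Focal losses generalise the other
    losses; the package verifies every reduction edge of that hierarchy
    numerically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    png,
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
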