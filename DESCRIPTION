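Package: dermwolf
Title: Gray Wolf Optimization for Dermoscopic Lesion Segmentation and
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for automated melanoma analysis built around an improved
    gray wolf optimizer (IGWO) with fitness-based omega regeneration.
    Includes dermoscopic image preprocessing (Gaussian denoising, DullRazor
    hair removal, lookup-table contrast stretching), Kapur-entropy multilevel
    thresholding driven by the optimizer with morphological post-processing,
    a compact convolutional neural network with a class-weighted training
    protocol and patient-grouped data splitting, IGWO-driven hyperparameter
    search over filter counts and dropout, imbalance-robust performance
    metrics, and a seeded synthetic dermoscopy generator so the whole
    pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
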