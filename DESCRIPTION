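Package: microQC
Title: Quality Control, Simulation and Augmentation Tools for Deep-Learning Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative quality-control metrics for evaluating deep-learning
    models applied to microscopy images: structural similarity (SSIM) and
    root-squared-error maps with mSSIM/NRMSE/PSNR summaries for image
    restoration, IoU-based semantic and instance segmentation scoring with
    optimal one-to-one instance matching, F1 and Panoptic Quality, and
    PASCAL-VOC style object-detection evaluation (precision-recall curves,
    AP, mAP).  Also provides a single-molecule localisation microscopy
    (SMLM) training-data simulator with a pixel-integrated Gaussian PSF and
    a Poisson/Gaussian camera noise model, a localisation post-processing
    chain (histogram rendering, spot extraction, event merging, drift
    estimation and correction by cross-correlation), deterministic D4
    augmentation for paired images and bounding boxes, loss-curve
    diagnostics, and a consolidated machine- and human-readable training
    report.  All tools work on multi-page TIFF stacks, ThunderSTORM-style
    localisation tables and PASCAL VOC XML annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    xml2,
    jsonlite,
    igraph,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
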