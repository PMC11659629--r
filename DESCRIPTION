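Package: mitodetect
Title: Two-Stage Mitotic Figure Detection for H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage framework for detecting mitotic figures in
    haematoxylin and eosin stained histology images. Stage one proposes
    cell-scale object masks on 1024x1024 tissue tiles via a pluggable
    promptable-segmentation backend with quality, stability and area
    filtering followed by non-maximum suppression; stage two classifies
    64x64 object crops with a compact convolutional network that fuses the
    object's binary mask into the first convolutional layer through a
    bias-free mask encoder. Includes whole-slide tiling with
    perimeter-based background removal, H&E optical-density stain
    deconvolution and stochastic concentration perturbation for colour
    augmentation, a distance-based detection evaluation protocol
    (precision, recall, F1 with multi-seed and ensemble aggregation),
    RANSAC affine registration utilities for transferring
    immunohistochemistry-derived annotations onto H&E slides, and a
    synthetic H&E scene generator with exact ground truth so the entire
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
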