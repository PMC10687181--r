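Package: hirschseg
Title: Patch-Based U-Net Segmentation and Zone Calling for Hirschsprung
    Disease Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for histology-based assessment of Hirschsprung disease
    from haematoxylin-eosin slide images. Provides a seeded synthetic
    slide generator with per-pixel ground truth, lossless multiclass mask
    input/output, exact 256x256 patch tiling and reconstruction, paired
    image/mask augmentation with an 80/20 split, two small U-Net semantic
    segmenters (ganglion cells plus normal nerves; hypertrophic nerves)
    trained with seeded Adam on a pixel-wise cross-entropy loss, and a
    two-model consensus decision table that calls each patch ganglionic,
    transition, or aganglionic and flags transition patches for
    pathologist review.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
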