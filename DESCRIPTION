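Package: equinode
Title: Stem-Node Detection and Hybrid Taxon Classification for Equisetum Specimen Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage image-analysis pipeline for discriminating Equisetum
    hyemale, E. laevigatum, and their sterile hybrid E. xferrissii from pressed
    herbarium specimen images. An anchor-grid object detector localizes aerial
    stem nodes and types each one as hyemale-like (H) or laevigatum-like (L,
    optionally hybrid F), using proxy labels inherited from the image-level
    taxon. Per-image statistics (mean score of the ten top-scoring detections
    per node type) feed simple classifiers (logistic regression, decision
    tree, k-nearest-neighbor) that assign the whole image to one of the three
    taxa. Includes VGG Image Annotator (VIA) v2 JSON input/output, rotation and
    crop augmentation with consistent bounding-box transforms, a synthetic
    pressed-specimen generator with ground-truth annotations for benchmarking
    without real scans, and evaluation utilities (detection matching, node and
    taxon confusion matrices, cross-type accuracy).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    rpart,
    nnet,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
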