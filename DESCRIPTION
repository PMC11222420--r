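Package: uroseg
Title: Two-Stage Urinary-System Segmentation for Non-Contrast CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for segmenting the urinary system (kidney,
    proximal/middle/distal ureter, urinary bladder) on non-contrast
    abdominopelvic CT. Stage one localises a region of interest from a coarse
    kidney-and-bladder segmentation at 4 mm resolution; stage two segments the
    five classes at 0.7 mm in-plane resolution with a multi-decoder residual
    U-Net trained under deep supervision (per-class binary cross-entropy plus
    Dice loss), random non-overlapping window sampling from the cropable
    centre area, and sliding-window inference with overlap-0.5 probability
    averaging. Includes NIfTI-1 and axial DICOM-series input, world-coordinate
    consistent resampling, a synthetic CT phantom generator with ground-truth
    masks for fully reproducible testing, Dice-coefficient evaluation and a
    fivefold cross-validation harness. The network, its backpropagation and
    the optimiser are implemented in R with Rcpp kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
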