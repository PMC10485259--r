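Package: splitreg
Title: Decoupled Unsupervised Deformable Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable registration of 2D and 3D scalar images
    by variable splitting. The joint objective (local normalized
    cross-correlation similarity plus a squared-gradient smoothness penalty on
    the displacement field) is decoupled into a similarity sub-problem and a
    quadratic smoothing sub-problem coupled by an auxiliary field. Both
    sub-problems are solved by small learnable operators trained in
    alternation: a light encoder-decoder similarity network that predicts the
    displacement field, and a residual denoising network built from parallel
    dilated convolutions that smooths it. An exact closed-form
    screened-Poisson solver for the smoothing sub-problem is provided both as
    a network-free classical mode and as a reference for testing. Includes a
    synthetic-data generator for desk-scale registration problems with known
    ground-truth deformations, Dice and endpoint-error evaluation, and NIfTI
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    Matrix,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
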