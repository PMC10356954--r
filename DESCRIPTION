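Package: marref
Title: Full-Reference Evaluation of CT Metal Artifact Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate CT metal-artifact-reduction (MAR) processing
    against a matched metal-free reference slice. Provides rigid 2D
    intensity-based registration of the reference to the metal-bearing
    image, automatic segmentation of metal, bone and tissue with gradient
    vector flow (GVF) active contours, Gaussian modelling of each region's
    Hounsfield-unit histogram, and four full-reference ratio metrics
    (FWHM and centroid ratios of the uncorrected and corrected images to
    the reference) with a near/far split around the metal. Includes a
    synthetic phantom simulator producing matched reference / uncorrected /
    corrected slice triples with ground-truth masks, so the whole pipeline
    is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    Matrix,
    EBImage,
    RNifti,
    png,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
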