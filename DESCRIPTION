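Package: respfit
Title: Deformable Registration and Goodness-of-Fit Prediction for Respirator Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts how well a filtering facepiece respirator conforms to an
    individual face from triangulated surface scans. Provides STL mesh input and
    output with vertex welding and cleaning, rigid iterative closest point (ICP)
    alignment, stiffness-regularised non-rigid ICP over a ladder of deformation
    levels, signed nearest-neighbour distance fields with area-weighted band
    scoring (gap, seal, indentation, +/-1 mm conformity), selection of the optimal
    deformation level, quantification of facial soft-tissue displacement from
    loaded and unloaded scans, landmark-based facial anthropometrics with
    correlation analysis, and a deterministic synthetic face/mask scene generator
    with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
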