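Package: gridwarp
Title: Geometric-Distortion Quality Assurance for Volumetric Scanners with a 3D Grid Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Interaction-free measurement of geometric distortion in volumetric
    (MR/CT) images of a 3D grid phantom. Provides synthetic phantom simulation with
    analytically known distortion fields, control-point localization by 3D
    normalized cross-correlation template matching, masked rigid pre-alignment,
    multiresolution stochastic B-spline free-form-deformation registration of a
    geometric reference volume onto a distorted acquisition, displacement-field
    statistics with a midpoint overfitting diagnostic, sequential registration
    parameter optimization, and QA report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
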