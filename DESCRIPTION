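Package: stemversion
Title: Predicting Femoral Stem Anteversion from Proximal-Femur Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Geometric measurement of femoral anteversion for preoperative
    planning of total hip arthroplasty in developmental dysplasia of the hip.
    Implements the axial-slice midcortical-line measurement (AM-CT), the
    simulated-osteotomy-plane midcortical-line and T-line measurements
    (AM-3D, AT-3D) and postoperative stem anteversion (PSA) from triangulated
    proximal-femur surface meshes and named anatomical landmarks, together
    with the cohort statistics used to compare the methods (mean differences,
    paired and two-sample t-tests, Pearson correlations, intraclass
    correlation coefficients).  A constructive parametric femur generator
    with exact ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
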