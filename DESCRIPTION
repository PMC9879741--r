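Package: ctcenterline
Title: Automatic CT Patient Positioning from Anterior-Posterior Localizers
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automatic estimation of CT patient vertical centering from a
    single anterior-posterior localizer (scout view). A convolutional
    encoder-decoder network synthesizes a 3D body volume from the 2D localizer;
    body and lung centerlines are then extracted by intensity thresholding,
    region shape evaluation and axis-aligned bounding boxes, and positioning
    error relative to the gantry isocenter is quantified (BCAP/BCMP/LCAP/LCMP).
    Includes a parametric chest-phantom generator with analytic fan-beam
    forward projection so the whole pipeline can be exercised and validated
    without patient data, plus DICOM/NIfTI input-output and the nonparametric
    cohort statistics used to compare automatic and manual positioning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
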