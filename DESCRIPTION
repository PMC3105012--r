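Package: craniomorph
Title: Automated Craniofacial Morphometry from T1-Weighted Head MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated three-dimensional craniofacial morphometry for
    brain-stripped T1-weighted head MRI. Builds a minimally biased group-wise
    average (atlas) of the head by iterative linear (6/9/12-parameter) and
    multi-resolution nonlinear registration, analyses the resulting
    deformation fields voxel-wise through Jacobian determinants with a general
    linear model and Gaussian random-field correction, propagates a 56-point
    facial landmark template to every subject through the inverse nonlinear
    transforms, and summarises landmark variation with anthropometric distance
    models and a principal-component point-distribution model including
    thin-plate-spline simulation of facial-feature modes. Ships a synthetic
    head-phantom generator with full ground truth (deformations, landmarks,
    planted sex/age/body-fat effects) so the whole pipeline can be exercised
    and validated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
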