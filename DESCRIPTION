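Package: purkinjemap
Title: Image-Based Reconstruction and Simulation of Cardiac Purkinje Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional cardiac Purkinje network structures by
    projecting flat, photograph-derived network images onto endocardial surfaces
    through a curvilinear cylinder chart, and validates the reconstructions with
    coupled ventricle-Purkinje monodomain simulations. Provides closed Bezier-spline
    approximating curves, the inverse-distance-weighted normal-average vector field
    and its trajectory-based curvilinear coordinate system, phase-field ventricular
    geometry handling with thin-shell endocardium extraction, texture projection of
    binary network images with coupling-site mapping, a two-variable excitable
    membrane model on masked 2D/3D grids with phase-field no-flux boundaries,
    two-way coupled 3D-3D and 3D-2D ventricle-Purkinje models, activation-map
    computation and comparison metrics, and deterministic synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    digest,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
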