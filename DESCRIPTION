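Package: phenopot
Title: Non-Destructive Growth Measurement of Potted Leafy Vegetables from
    Multi-View Colored Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs potted leafy vegetables (lettuce and similar
    green-leaf crops) from turntable multi-view colored point clouds and
    measures their key growth parameters without touching the plant.
    Per-view clouds are registered into a common turntable frame with
    marker-based rigid alignment, split into plant and non-plant points by
    quadric decision surfaces in HSI color space, cleaned of layered
    time-of-flight artifacts (multi-view interference elimination) and
    local noise (moving least squares), and triangulated into a filtered
    leaf-surface mesh.  From the mesh and the truncated-cone pot model the
    package reports relative and absolute plant height, total and
    grid-sampled projected leaf area, and the grid-sampled volume of the
    union of overlapped tetrahedra, with optional calibration models
    mapping sensor measurements to reference scales.  A synthetic scene
    generator with analytic ground truth (parametric leaf patches,
    truncated-cone pot, soil disk, multi-view duplication with layered
    offsets and Gaussian noise) replaces the capture hardware for testing
    and validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
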