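Package: canophot
Title: 3D Canopy Photosynthesis Modelling and Factorial Trait Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional-structural simulation of maize-like canopies:
    labelled point-cloud denoising, extraction of editable leaf vector
    models (midrib axis plus per-station width vectors), trait adjustment
    (leaf length, width, number, curvature, insertion angle), lofted
    triangle meshing, row-grid canopy assembly, Monte-Carlo forward ray
    tracing of direct and diffuse photosynthetically active radiation with
    periodic lateral boundaries, non-rectangular hyperbola leaf
    photosynthesis with light-response curve fitting, diurnal canopy CO2
    uptake integration, SPAD-based leaf optics, and inclusion-exclusion
    factorial dissection of the contributions of plant architecture, leaf
    photosynthetic parameters, and leaf optical properties to canopy
    photosynthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
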