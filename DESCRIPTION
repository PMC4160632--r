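Package: vibroskull
Title: Harmonic Finite-Element Simulation of Skull Vibration for Bone Conduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A harmonic forced-response finite-element engine for viscoelastic
    solids meshed with linear tetrahedra, aimed at bone-conduction hearing
    research. Materials carry complex, frequency-dependent Young's moduli
    (storage modulus plus a constant or linear-in-frequency loss factor), so
    damping enters through the imaginary part of the stiffness matrix. The
    package assembles consistent mass and complex stiffness matrices, solves
    the free-free forced-response equation over a frequency grid by direct
    sparse factorization, and derives mechanical point impedance, three-axis
    cochlear-bone accelerations, unwrapped phase, and group delay. A built-in
    synthetic two-layer spherical skull surrogate (an outer bone shell lined
    internally with polyurethane, mass-calibrated per region) stands in for
    image-based skull geometry; Gmsh MSH ASCII meshes can be imported and
    displacement fields exported as legacy VTK. A config-driven scenario
    runner reproduces modulus, loss, and density parametric sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo:
    Rcpp,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
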