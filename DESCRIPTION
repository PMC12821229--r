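Package: breastdeform
Title: Prone-to-Supine Breast Deformation Modeling with Visco-Hyperelastic
    Finite Elements
Version: 0.1.0
Authors@R:
    person("Scientific", "Software", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Patient-specific simulation of prone-to-supine breast
    deformation for surgical planning. Implements a total-Lagrangian
    explicit-dynamics finite-element solver on linear tetrahedra with a
    neo-Hookean visco-hyperelastic material (single- or multi-term Prony
    relaxation), rigid chest-wall contact with Coulomb friction, symmetry
    boundary conditions, and a nipple-based stopping criterion. Includes
    synthetic breast phantom generation, STL and Slicer markups I/O,
    intermammary rigid alignment with geodesic boundary transfer,
    simulated-annealing calibration of the breast shear modulus, and
    tumor localization metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
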