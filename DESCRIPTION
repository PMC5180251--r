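Package: fgmvessel
Title: Functionally Graded Artificial Vessel Elastodynamics with Reduced-Order
    Fluid-Structure Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the axisymmetric elastodynamic response of thick-walled
    blood vessels whose wall properties vary radially, including functionally
    graded (Dacron-to-polyurethane) artificial grafts and the three-layer
    natural arterial wall. Provides a differential quadrature (DQM) collocation
    solver together with an independent finite-difference discretization for
    cross-validation, a reduced-order pulsatile blood pressure model (Poiseuille
    gradient with a distensible thin-wall closure), a partitioned two-way
    fluid-structure coupling loop with under-relaxation, and post-processing of
    radial displacement, circumferential stress and von Mises stress fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    yaml,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
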