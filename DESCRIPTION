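Package: piezobone
Title: Strain-Adaptive Bone Remodelling Simulation with Piezoelectric
    Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Plane-strain finite element simulation of strain-adaptive
    bone remodelling in a two-dimensional proximal femur, without and
    with piezoelectric coupling.  Density-dependent isotropic elasticity,
    a strain-energy-density remodelling stimulus integrated with an
    explicit Euler scheme, gait load scheduling with parabolic joint and
    abductor tractions, therapeutic surface-charge stimulation during
    reduced physical activity, Gmsh MSH v2 mesh input, legacy VTK result
    output, programmatic bar and femur-like benchmark geometries with
    analytic oracles, and Hounsfield-unit calibration utilities for
    CT-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
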