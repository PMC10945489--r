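Package: aquacoex
Title: Liquid-Vapor Coexistence and Evaporation Analysis for Rigid Three-Point Water Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for liquid-vapor phase behaviour of rigid
    three-point water models: derived electrostatic moments (dipole and
    tetrahedral quadrupole) from model geometry and charges, slab density
    profiles with periodic re-centering and hyperbolic-tangent interface
    fits, critical-point estimation from the universal scaling law and the
    law of rectilinear diameters with block-splitting uncertainties,
    evaporation enthalpy and saturation-pressure thermodynamics, detection
    of spontaneous evaporation on isobaric heating ladders, density-maximum
    fits, and cross-model correlation statistics. Includes seeded synthetic
    generators for every input so the full pipeline is testable without a
    molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
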