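Package: monofilm
Title: Structural and Thermodynamic Analysis of Lipid Monolayers and Supported Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for Langmuir monolayers and electrode-supported
    bilayers of bacterial-membrane lipid mixtures. Implements exact specular
    reflectivity of stratified interfaces (Parratt recursion with Nevot-Croce
    roughness and dq/q resolution smearing), a two-slab lipid-monolayer model
    with X-ray and neutron contrast generation (tail deuteration, H/D
    exchange), grid-scan multi-contrast co-refinement with profile-likelihood
    confidence ranges and diffraction-aware model selection, grazing-incidence
    diffraction reduction and 2D unit-cell/tilt analysis, surface
    pressure-area isotherm compressibility and phase-transition extraction,
    chronocoulometric charge-density and film-pressure thermodynamics,
    PM-IRRAS band deconvolution with chain-tilt estimation, and seeded
    synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
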