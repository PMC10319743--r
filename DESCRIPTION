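Package: bonewave
Title: Microwave Bone-Fracture Detection: Tissue Electromagnetics, Sensor
    Design Calculators, and Raster-Scan Phase Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling toolkit for dual-polarized microwave bone
    fracture detection at 2.45 GHz. Provides a human-tissue dielectric registry
    with complex propagation constants and per-layer attenuation budgets for
    layered lossy media; design calculators for a reactive impedance surface
    (reflection phase and its closed-form inverse) and a via-loaded dielectric
    matching lens (discrete-dipole effective-medium mixing, geometric-mean
    matching, quarter-wave thickness); a cylindrical multilayer near-field
    mode-matching solver built on complex-argument Bessel and Hankel functions;
    and a ray-based raster-scan simulator of a transceiver pair over an arm
    phantom that constructs transmission-phase difference images of bone cracks
    and classifies their orientation from two orthogonal polarizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
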