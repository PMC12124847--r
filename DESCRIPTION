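Package: epgspoil
Title: Extended-Phase-Graph Simulation of RF Spoiling in Gradient-Echo MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the pseudo steady state of radiofrequency-spoiled
    gradient-echo (FLASH/SPGR) sequences with the extended phase graph (EPG)
    formalism including diffusion attenuation of configuration states, and
    quantifies how well a given RF phase difference increment approximates
    ideal spoiling. Provides the elementary EPG operators with an
    isochromat-ensemble cross-check, the quadratic phase cycle and a
    configurable one-TR gradient schedule, the Ernst closed forms, the
    flip-angle-averaged deviation metric epsilon, parameter-space and
    voxel-size sweep pipelines, and a synthetic phantom-measurement generator
    with Rician ROI noise and Ernst-angle normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
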