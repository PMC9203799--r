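Package: neurofield
Title: Bidomain Simulation of Epileptic Seizure Waves in Head Tissue
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples the bidomain tissue equations with the Cressman
    ion-concentration neuron model to simulate seizure-like wave propagation
    in layered head geometries (grey matter, white matter, cerebrospinal
    fluid, skull, scalp). Provides a graded conforming triangulation of an
    idealized two-dimensional head slice with per-tissue conductivity
    tensors and white-matter anisotropy, first-order Lagrange finite-element
    discretization with second-order operator splitting in time, standalone
    point-neuron integration in stable and seizure-like parameterizations,
    and a spectral-analysis pipeline (threshold spike counting, burst
    segmentation, Welch power spectral density, and band-restricted
    power-law exponent fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
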