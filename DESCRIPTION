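Package: fatenet
Title: Attractor Dynamics of Transcription Factor-Enhancer Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of cell-identity dynamics through the
    competition of enhancers for transcriptional machinery. Transcription
    factor (TF) expression feeds back on enhancer chromatin, enhancer
    activation follows a Boltzmann (softmax) competition sharpened by an
    effective inverse temperature, and cell types arise as attractors of
    the resulting gradient-like flow. The package parameterizes networks
    directly from terminal cell-type expression profiles, simulates
    deterministic and stochastic identity dynamics, enumerates and
    classifies attractors (terminal types and progenitor-like subset
    averages), reproduces hierarchical differentiation by annealing of the
    inverse temperature, scores and verifies TF-overexpression
    reprogramming recipes, and provides closed-form results for critical
    inverse temperatures and the specification gain of closely related
    cell-type families, each cross-validated against numerical oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
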