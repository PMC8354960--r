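Package: choicerep
Title: Simulation and Preregistered Analysis of Value-Based Choice Repetition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design, simulate and analyse a value-based decision game
    used to study choice repetition (hysteresis) under transcranial direct
    current stimulation (tDCS). Provides an indifference-point-calibrated
    trial-design engine (psychometric fits, bias/target triplets,
    counterbalanced session plans), a two-population attractor-network
    synthetic participant with residual-activity decay and a polarization
    parameter, and the full preregistered statistical pipeline
    (bias-success filtering, repetition index, log decision-time contrasts,
    paired t tests, Hedges g, repeated-measures ANOVAs with partial eta
    squared, Holm correction, sham pooling, and noncentral-t power
    analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
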