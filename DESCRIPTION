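Package: chemoflux
Title: Chemostat Multiomics Integration: Allocation Laws, Enzyme-Constrained
    Flux Analysis and Thermokinetic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative analysis of steady-state chemostat
    multiomics data from budding yeast: proteome and transcriptome
    functional-group allocation laws with piecewise-linear fits and
    critical-rate detection, absolute quantification calibrations (iBAQ
    spike-in regression, copies-per-cell conversion, FPKM calibration),
    correlation and set-enrichment statistics, flux balance and flux
    variability analysis with GECKO-style enzyme constraints on a
    JSON-described metabolic model, a thermodynamics-derived loglinear
    kinetic model with Markov chain Monte Carlo inference of intrinsic
    turnover numbers, and hierarchical regulation plus functional
    phosphosite analysis. A seeded synthetic-data generator reproduces the
    statistical structure of a glucose-limited chemostat study so every
    stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
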