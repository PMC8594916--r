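Package: ragrowth
Title: Growth-Mode Inference and Rate-Limiting Apical Growth Kinetics for
    Single-Cell Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the single-cell growth law of apically
    growing bacteria (such as Corynebacterium glutamicum) from time-lapse
    lineage data. Implements conditional "wavefront" averaging of elongation
    trajectories: per-timepoint linear fits of cell length against birth
    length yield average elongation trajectories and rate curves per birth
    length, with measurement-noise (regression-dilution) bias correction,
    division-event truncation, smoothing, numerical differentiation and
    bootstrap confidence bands. Includes the rate-limiting apical growth
    (RAG) kinetic model with Michaelis-Menten elongation and first-order or
    self-accelerated transglycosylase recruitment, nonlinear fitting of
    elongation-rate curves, population-level adder/sizer diagnostics, an
    exponential-growth consistency test, multi-generation population
    simulations contrasting asymptotically linear and exponential growth,
    quantification of polar fluorescence intensity profiles (demographs,
    background correction, septum-onset detection), and a fully seeded
    synthetic colony generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
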