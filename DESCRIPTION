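Package: tiledep
Title: Tiling-Array Analysis of Ribonuclease Depletion Experiments
Version: 0.1.0
Authors@R: person("tiledep", "developers", role = c("aut", "cre"),
    email = "tiledep@example.org")
Description: A pipeline for strand-specific tiling-microarray depletion
    experiments in bacteria: probe-to-gene median aggregation,
    least-variant-set between-array normalization, per-gene t-tests with
    local false discovery rate estimation, amplitude-cutoff break-point
    selection, cross-study concordance of differential gene lists,
    functional-category over/under-representation, expression-level
    stratified projection of direct versus indirect effects, and mRNA
    half-life estimation from rifampicin decay series. Includes a
    synthetic-data generator emulating a two-condition depletion design
    so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
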