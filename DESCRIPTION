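Package: oscmotif
Title: Gene Expression Driven by Oscillatory Transcription Factors in
    Regulatory Network Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation and closed-form stationary analysis of
    gene expression controlled by oscillatory transcription factors through
    direct regulation, two-step cascades and the eight feed-forward loop
    motifs with AND/OR logic gates. Threshold (step-function) gene
    activation yields piecewise-exponential dynamics that are solved
    exactly segment by segment; stationary-regime statistics (time-averaged
    expression, cycle extrema, activation delays and duty fractions) are
    obtained as fixed points of the one-period return map. A numerical
    integrator for the step-function and Hill-function model variants
    serves as an independent cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    pracma,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
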