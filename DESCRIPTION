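Package: lfqassess
Title: Length-Based Stock Assessment from Length-Frequency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Length-based demographic and exploitation assessment for
    data-limited crustacean and fish stocks. Implements ELEFAN
    (electronic length-frequency analysis) restructuring and scoring of
    monthly length-frequency data, von Bertalanffy growth estimation by
    a genetic algorithm with bootstrap confidence intervals, the
    linearized length-converted catch curve for total mortality, a
    thirteen-formula empirical natural-mortality suite, logistic
    gear-selectivity estimation from catch-curve capture probabilities,
    and Beverton-Holt relative yield- and biomass-per-recruit reference
    points (E10, E50, Emax) with a length-structured alternative. An
    individual-based simulator of a depth-structured trap survey
    provides a fully known test substrate, and a configurable pipeline
    reproduces the complete analysis sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
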