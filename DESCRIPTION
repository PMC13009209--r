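Package: remgate
Title: REM Sleep Gating Integrity Analysis and the MOBIUS Misbinding Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the containment of REM-sleep simulation:
    synthetic generators for hypnograms, slow-oscillation/spindle coupled
    EEG-like epochs and two-group cohort feature tables; extraction of three
    oriented gating features (SO-spindle coupling vector length, REM mean
    bout duration, REM 1/f steepness); REM Gating Integrity composites
    (control z-scores, weakest-link RGI_min, signed shrinkage-covariance
    distance-to-control); small-sample inference suited to n = 4 per group
    (Hedges' g, exact randomisation tests, stratified BCa bootstrap); and
    the MOBIUS logistic model of simulation-to-memory misbinding with
    phase-space mapping and maximum-likelihood parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    ggplot2
Config/testthat/edition: 3
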