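Package: echoprey
Title: Prey-Field Analysis from Recreational-Grade Echosounder Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the relative abundance of potential prey
    (RAPP) of coastal marine predators from uncalibrated, recreational-grade
    echosounder (RGE) recordings. Converts 8-bit ping exports to relative-dB
    echograms, selects and applies a time-varied-gain (TVG) correction using
    calibration-sphere returns and CTD-derived seawater absorption, removes
    seabed and range-dependent background noise, detects fish schools with a
    SHAPES-style threshold/link/minimum-dimension algorithm, applies
    beam-geometry corrections to school morphology, summarises surveys into
    cumulative school area (c.SchA) and track proportion (Prop.Track)
    metrics, and fits negative-binomial generalized additive mixed models of
    predator counts against those metrics. Includes a synthetic-data
    generator that plants schools, seabed, noise and calibration-sphere
    drops with known truth so the whole pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    geosphere,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
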