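Package: pdgait
Title: Gait Analysis and Transmission Quality Control for Wearable
    Accelerometer Networks
Version: 0.1.0
Authors@R:
    person("PERFORM", "Reimplementation", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Analysis pipeline for tri-axial accelerometer body-area
    networks used in ambulatory monitoring of Parkinson's disease gait.
    Reads timestamped packet streams from five body-worn sensors (belt,
    wrists, legs) sampled at 62.5 Hz, detects wireless transmission gaps
    and summarises burst-error statistics, trims unstable start-up
    periods, normalises and grids the signals, segments walking bouts
    with a transparent window classifier, and computes per-bout gait
    descriptors: sample entropy, step frequency, stride length via the
    inverted-pendulum model, walking velocity and stride-to-stride
    variability. Includes a synthetic-data generator that emulates
    healthy and parkinsonian gait plus the wireless packet-loss process,
    so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    graphics,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
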