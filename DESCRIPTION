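Package: meaburst
Title: Network-Burst and Irregularity Analysis for Micro-Electrode Array
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for developing neuronal network activity
    recorded on micro-electrode arrays (MEAs): extracellular spike detection
    with a median-based peak-to-peak threshold, separation of network-burst
    and background action potentials, network-burst detection from a
    Gaussian spike-density trace, spike- and burst-timing irregularity
    statistics (CV of interspike and interburst intervals, Fano factor,
    rate-independent burst irregularity), spike-train autocovariance with
    half-width extraction, and per-age two-condition group comparison with
    rank tests and false-discovery-rate control.  Includes a synthetic
    generator for bursting spike-train sets and raw voltage traces so that
    every stage of the pipeline can be validated against planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
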