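Package: minsignet
Title: Stochastic Simulation of a Minimal Two-Pathway Signaling Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact Gillespie simulation and chemical-Langevin integration of a
    minimal four-reaction signaling network in which a one-step deterministic
    pathway competes with a fast-slow-fast stochastic cascade for activation of
    a shared downstream species, a minimal model of apoptosis signaling.
    Includes analytic regime classification (deterministic, mixed, stochastic)
    as the stimulus strength varies, population-level analysis (activation
    times, Fano factors, snapshot distributions with modality labels, pathway
    attribution, phase-diagram scans), and a command-line interface with tidy
    TSV output for reproducible in-silico cell populations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
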