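Package: cardiostop
Title: Simulation and Analysis of Cardiac-Coupled Stop-Signal Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing stop-signal experiments in
    which visual distractors are time-locked to the cardiac cycle. Provides a
    synthetic-data generator (autocorrelated RR-interval series with
    controlled heart-rate variability, template-based ECG, a race-model agent
    driving an adaptive stop-signal-delay staircase, and multichannel EEG with
    injected event-related components and a cardiac field artifact), plus the
    full analysis chain: staircase tracking and timing-precision audits,
    integration-method SSRT estimation, ERP epoching with baseline correction
    and amplitude-based rejection, cardiac-field-artifact estimation and
    subtraction, ECG-coherence-based component ranking and removal, ROI
    amplitude extraction, spatiotemporal cluster-based permutation testing,
    and mixed-model condition-effect estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
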