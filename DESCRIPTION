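Package: syncond
Title: Phase-Resolved Synaptic Conductance Reconstruction from
    Intracellular Recordings in Rhythmic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts and separates phase-resolved excitatory and inhibitory
    synaptic conductance profiles from single-neuron intracellular recordings
    in rhythmically active networks (central pattern generators and other
    oscillatory circuits). Implements trace preprocessing (moving-median spike
    removal, anti-aliased downsampling, burst-onset detection on the rectified
    and integrated reference nerve signal, cycle-phase assignment, epoch
    quality control), phase-binned current-voltage linear regression for total
    conductance and effective resting potential, decomposition into inhibitory
    and excitatory components given reversal potentials, dynamic-component and
    leak estimation with error propagation and one-tailed z-tests, reversal
    potential estimation from wedge-diagram boundary lines, robustness scans
    over reversal potentials and recording epochs, and functional-connectome
    motif inference from significant conductance components. A conductance
    based single-compartment neuron simulator with canonical respiratory
    firing-phenotype fixtures provides ground truth for parameter-recovery
    validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
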