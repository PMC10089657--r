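Package: elmaze
Title: Single-Unit Analysis of Hippocampal Activity During Anxiogenic Maze
    Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for analysing single-unit recordings
    from rodents exploring elevated mazes with anxiogenic (open, unwalled)
    locations. Converts 2D tracking into linearised positions, speeds and
    directional trials; builds occupancy-normalised 2D and linear firing-rate
    maps with Gaussian smoothing; computes per-neuron spatial information,
    sparsity, coherence, directional place-field similarity and peak-density
    maps with bootstrap nulls; classifies units from waveform statistics;
    detects sharp-wave ripples from the local field potential; residualises
    spiking against running speed with a linear model; and predicts the
    extent of open-arm exploration from pre-entry population activity using
    a linear support-vector machine with wrapper pair selection,
    leave-one-out cross-validation and a permutation null. A seeded
    synthetic-session generator (shuttling trajectories, inhomogeneous
    Poisson place cells, ripple-embedded LFP) makes every stage testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
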