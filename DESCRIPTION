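Package: hippoephys
Title: Hippocampal Electrophysiology Analysis: Synaptic Events, Oscillations,
    Sharp-Wave Ripples and Unit Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for in vivo hippocampal
    electrophysiology. Detects and quantifies spontaneous postsynaptic
    currents from voltage-clamp sweeps, parameterizes local field potential
    spectra into aperiodic (1/f) and periodic components with peak-only band
    powers and band ratios, detects oscillation episodes with a
    background-corrected wavelet threshold, computes spike/event-to-phase
    locking with circular statistics and the Rayleigh test, classifies
    sorted extracellular units by waveform width and autocorrelogram shape,
    quantifies burst firing, detects sharp-wave ripples with a control-band
    specificity gate, and identifies putative PV+ basket cells from
    peri-ripple firing and theta phase preference. Includes a synthetic-data
    generator with ground truth so every detector can be validated without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
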