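Package: rootwave
Title: Wavelet Analysis of Fictive Locomotor Rhythms in Ventral Root Neurograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drug-induced locomotor-like rhythms recorded
    extracellularly from spinal ventral roots under optogenetic perturbation.
    Provides artifact correction and the filter cascades that produce integrated
    neurograms and slow locomotor drive potentials; complex-Morlet wavelet
    spectrograms with instantaneous-frequency ridge extraction and cross-channel
    phase series; baseline normalization and per-experiment aggregation with
    trial-validity rules; pointwise bootstrap t-tests between cohorts of
    experiment-averaged time series with tiered significance coding; a
    ground-truth synthetic fictive-locomotion generator for calibration and
    parameter-recovery studies; and a small toolkit for intracellular motoneuron
    sweeps (spike counts, input resistance, collision-protocol electrical
    coupling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    data.table,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
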