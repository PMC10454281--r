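Package: motoreeg
Title: Movement-Related EEG Spectral, Phase and Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for movement-locked EEG: surface-Laplacian
    current source density via Perrin spherical splines, complex Morlet
    time-frequency decomposition on a logarithmic frequency grid,
    event-related spectral perturbation (single-trial gain model) and
    inter-trial coherence, debiased weighted phase-lag-index functional
    connectivity with weighted graph metrics (node strength, global and
    local efficiency, proportional thresholding), and cluster-based
    permutation statistics over channel-frequency-time maps. Includes a
    synthetic two-group cohort generator with known ground-truth phase
    locking, spectral perturbation and lagged coupling for parameter
    recovery, and readers for Biosemi BDF / EDF recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    deldir,
    digest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
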