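Package: gammatrio
Title: Decomposition and Analysis of Three Narrowband Gamma Rhythms in
    Visual Cortex Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-trial visual-cortex recordings
    (local field potentials and spike trains) driven by gratings of varying
    spatial frequency. Estimates multitaper power spectra and spike-field
    coherence, decomposes the spatial-frequency-by-frequency power surface
    into a 1/f aperiodic baseline plus three Gaussian gamma components
    (low, medium, high gamma) with Naka-Rushton peak-frequency and
    difference-of-Gaussians amplitude profiles, quantifies spatial-frequency
    tuning (cutoff SF, SF selectivity), aligns laminar-probe channels on a
    normalized relative-depth axis and bootstraps per-band power-peak
    depths, and decodes object edge versus surface from gamma-band power
    with an L1-regularized logistic decoder. Includes a synthetic-data
    generator with known ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
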