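Package: frispike
Title: Finite-Rate-of-Innovation Sampling and Spike Inference from
    Calcium Fluorescence Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sampling and perfect reconstruction of streams of Diracs and
    decaying exponentials using exponential-reproducing kernels (E-splines
    and Gaussian filters), annihilating-filter (Prony) recovery,
    Cadzow low-rank Toeplitz denoising, total-least-squares and
    matrix-pencil estimation, and a sliding-window streaming detector with
    location-histogram consistency.  Includes a synthetic generator for
    two-photon calcium fluorescence traces (Poisson spike trains convolved
    with a decaying exponential plus Gaussian noise) and a double-consistency
    spike-inference pipeline for such traces, with a small command-line
    interface for simulation, reconstruction and spike detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
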