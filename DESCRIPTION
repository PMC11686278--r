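Package: estrocal
Title: Estrous-Cycle Photometry, Drinking-Bout, Ephys and Calibration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying estrogen-state effects on
    binge alcohol drinking and BNST CRF neuron physiology: two-channel
    fiber-photometry preprocessing (median/lowpass denoising, isosbestic
    motion correction, whole-trace z-scoring), lickometer bout detection
    and peri-event alignment, calcium-transient detection with
    reference-normalized amplitude distributions, spontaneous PSC
    pharmacology metrics and responder classification, 1/C-weighted
    calibration curves with LLOQ determination, single-nucleus receptor
    expression fractions, and group-comparison statistics with
    Holm-Sidak correction. A synthetic-data module generates every input
    with known ground truth so each stage is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
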