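Package: mdselect
Title: Measurement Descriptor Generation and Selection for Biopolymer Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts heterogeneous spectroscopic and thermal measurement curves
    (solid-state 1H/13C NMR, time-domain NMR solid-echo decays, ATR FT-IR, DTG)
    of keratin biopolymers into scalar "measurement descriptors" via
    Savitzky-Golay second-derivative pre-treatment, even and logarithmic
    binning, PCA score retention, and Voigt/Abragam curve deconvolution; then
    selects the descriptor subsets most predictive of tensile properties by
    importance-guided recursive elimination under repeated 10-fold
    cross-validation with random forest and partial least squares regression,
    reporting the consensus of the two algorithms. Ships a synthetic multimodal
    data generator with planted ground truth so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    randomForest,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    vegan
Config/testthat/edition: 3
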