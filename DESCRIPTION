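Package: cmapnet
Title: Simulated Compound Muscle Action Potentials and Recurrent-Network
    Inference of Conduction Velocity Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of compound muscle action potential (CMAP)
    waveforms by latency-shifted superposition of a single motor unit
    potential across a 200-axon median-nerve population under six
    demyelination patterns with and without conduction block, and inverse
    inference of the per-velocity axon-count histogram from a CMAP waveform
    using recurrent neural networks (simple RNN, LSTM, GRU, unidirectional
    or bidirectional, one to three layers) trained with Adam on mean squared
    error. Includes corpus generation with train/test splitting,
    architecture-grid and per-group evaluation reports, and plain-text
    serialization of templates, histograms, corpora and model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
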