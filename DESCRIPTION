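Package: profileBLSTM
Title: Protein Remote Homology Detection with Bidirectional LSTMs over
    Profile-Derived Pseudo Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects remote protein homology at the superfamily level with a
    bidirectional long short-term memory network. Query sequences are rewritten
    into pseudo proteins carrying the most favoured residue of a PSI-BLAST
    position-specific scoring matrix at every position, encoded as sliding-window
    one-hot matrices, and scored by a four-layer network (bidirectional LSTM,
    time-distributed dense fusion of every intermediate hidden state, single
    logistic output node) trained with RMSprop on binary cross-entropy. Includes
    SCOP-style family-holdout benchmark split construction, ROC and ROC50
    evaluation with a paired t-test for method comparison, per-position learned
    feature extraction with a t-SNE embedding for visualization, and a synthetic
    planted-motif sequence/PSSM generator so the whole pipeline is exercisable
    without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
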