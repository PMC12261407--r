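Package: replitimer
Title: Predicting High-Resolution DNA Replication Timing from Chromatin Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 16-fraction (high-resolution) Repli-Seq replication
    timing profiles for 50-kb genomic bins from nine per-bin features (six
    histone marks, GC content, gene density, and two-stage early/late
    replication timing) using a bidirectional multilayer LSTM trained with
    Kullback-Leibler divergence loss. Includes the full feature-assembly
    pipeline from standard genomic file formats, label filtering and
    normalization, a five-metric evaluation suite on probability and
    cumulative-distribution space, quantile and regression baselines,
    sigmoid replication-kinetics fitting (T_rep, T_width), chromosome-wise
    autocorrelation analysis, and a seeded synthetic-data generator for
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    minpack.lm,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
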