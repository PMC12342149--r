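Package: GraphEMA
Title: Graph-Transformer Estimation of Protein Complex Model Accuracy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the global accuracy (true TM-score) of protein complex
    structural models (decoys) without the native structure. Decoy pools are
    represented as pairwise structural-similarity graphs whose nodes carry
    consensus and single-model quality features; cluster-balanced subgraphs of
    bounded size are sampled so that large groups of mutually similar mediocre
    models cannot dominate consensus scoring, and a graph transformer with
    edge-biased multi-head attention predicts a per-decoy quality score on each
    subgraph. Per-subgraph predictions are aggregated (mean or median),
    optionally repeated and ensembled across checkpoints. Includes the average
    pairwise-similarity consensus baseline, CASP-style evaluation metrics
    (Pearson and Spearman correlation, ranking loss, quantile-thresholded AUC,
    z-score summation), by-target cross-validation utilities, and a synthetic
    decoy-pool generator with planted structural clusters for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
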