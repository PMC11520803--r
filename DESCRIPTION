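Package: ctibench
Title: Gold-Standard Benchmarking Toolkit for Compound-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for constructing and evaluating gold-standard benchmark
    datasets for compound-target interaction (CTI) prediction. Provides
    Tanimoto max-min negative sampling, warm-start and cold-start
    cross-validation splits, mutation-aware and label-reversal evaluation
    designs, rotatable-bond dataset filters, compound featurization (SMILES
    one-hot, concatenated 2D fingerprints, conformer-based 3D fingerprints,
    atom interaction graphs), target featurization (sequence one-hot,
    physicochemical PCA, weighted residue interaction graphs, pretrained
    embedding loading), reference neural architectures (graph attention v2
    layers, convolution-pooling towers, fingerprint MLP towers, global-window
    sequence towers) with a seeded SGD training loop, classification metrics
    with a random-prediction baseline, and a synthetic data generator so the
    full pipeline is testable at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
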