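Package: ppistack
Title: Stacked Ensemble Prediction of Protein-Protein Interaction Sites
    from Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts which residues of a protein participate in
    protein-protein interaction interfaces, using sequence information
    only. Per-residue features from six encoders (one-hot, entropy
    density, physicochemical descriptors, hydropathy indices, PSSM
    profile rows, and a windowed pseudo amino acid composition) are
    paired into three feature modules; each module feeds a base
    classifier that aggregates sliding-window context with a 1-D
    convolution block and masked multi-head self-attention, keeps the
    targeted residue feature on a separate path, and scores residues
    with a batch-normalized fully connected head. Severe class
    imbalance is handled by partitioning the non-site majority into M
    near-balanced subsets cycled during training, and the three base
    classifiers are combined by stacking with a configurable
    meta-learner. Includes a synthetic planted-motif sequence generator
    with mock PSSMs so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    Biostrings,
    class,
    jsonlite,
    pROC,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
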