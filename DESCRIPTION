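Package: DIPK
Title: Drug Response Prediction Integrating Gene Interaction Networks,
    Expression Profiles and Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the DIPK framework for predicting the natural-log
    IC50 of (cancer cell line, drug) pairs. Cell lines are represented by
    an interactome feature (the mean graph-auto-encoder embedding of the
    most highly expressed genes) and a transcriptome feature (a denoising
    auto-encoder latent vector); drugs are represented by per-atom vectors
    from a neighbour-attention message-passing network with gated
    recurrent unit updates, optionally pre-trained with pairwise
    half-graph discrimination and attribute masking. The modalities are
    fused through multi-head attention and a fully connected head trained
    with mean squared error. Includes the cold-start cross-validation
    protocols (cell-disjoint, drug-disjoint and doubly disjoint folds),
    the DEM/DIM ablation variants, and a synthetic-fixture generator with
    a planted response function for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    igraph,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
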