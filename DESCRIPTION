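Package: mvddi
Title: Multi-View Drug-Drug Interaction Prediction from Molecular Graphs
    and Knowledge-Graph Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) by fusing two views of
    each drug: a molecular-structure view encoded with a graph isomorphism
    network (GIN, sum aggregation with concat-over-layers readout) over
    SMILES-derived heavy-atom graphs, and a knowledge-graph view encoded
    with RotatE complex-rotation embeddings trained by negative sampling.
    The two 100-dimensional views are combined by a multi-level latent
    fusion block (convolutional concatenate-level branches, autoencoder
    scalar-level branches, and their elementwise sum) refined with a
    multi-head self-attention encoder, and scored for drug pairs by a
    dense classifier supporting binary and multi-class DDI tasks with
    label-smoothing cross-entropy. Includes a seed-deterministic synthetic
    world generator (toy SMILES, a toy knowledge graph with planted
    symmetric, inverse and compositional relations, and planted DDI
    labels) so every stage is testable offline, plus readers and writers
    for the tab-separated exchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
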