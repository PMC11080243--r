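Package: ppitype
Title: Multi-Label Prediction of Protein-Protein Interaction Types with
    Global and Egonet-Kernel Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies edges of a protein-protein interaction (PPI)
    network into seven interaction categories (reaction, binding,
    post-translational modification, activation, inhibition, catalysis,
    expression).  Vertex representations fuse a global Graph Isomorphism
    Network (GIN) encoder with a local subgraph-as-kernel encoder that
    runs a shared GIN over every vertex's k-hop egonet and gates member
    embeddings by encoded path distances.  Training uses an asymmetric
    focal-style loss with a probability margin to handle category
    imbalance, and evaluation supports random, breadth-first and
    depth-first edge partitions that concentrate test edges around
    unseen proteins.  Includes a seeded stochastic-block-model generator
    of PPI-like multi-label graphs, imbalance-aware micro/macro/weighted
    metrics, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
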