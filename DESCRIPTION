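Package: pigmentnet
Title: Disease-Gene and Protein Interaction Network Analysis for Skin Pigmentation Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates gene-disease association tables into a bipartite pigmentation
    diseasome, builds confidence-filtered protein-protein interaction (PPI)
    networks from STRING-style scored edge tables, clusters them with a
    from-scratch Markov Cluster (MCL) algorithm, profiles functional classes
    with hypergeometric over-representation statistics under Benjamini-Hochberg
    FDR control, greedily expands seed networks against a background
    interactome, and overlays label-free quantification (LFQ) proteomics
    abundances onto the result. Ships seeded synthetic-data generators with
    planted structure so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
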