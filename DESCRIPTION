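Package: keratinscreen
Title: Multi-Step Prediction of Candidate Keratinases from Annotated
    Bacterial Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative pipeline for nominating candidate keratinases (or
    any target hydrolase class) from annotated bacterial proteomes.
    Putative proteases are mined from consolidated functional annotations
    by keyword matching, assigned to MEROPS-style peptidase families by
    reciprocal best hit, clustered into protease orthogroups, linked to
    functionally characterized reference enzymes through a sequence
    similarity network with weighted Louvain community detection, embedded
    from fused subcellular-localization scores (PCA and t-SNE followed by
    DBSCAN grouping), and finally screened by occupancy-filtered
    phylogenetics with equal-rates Markov ancestral state reconstruction
    and a three-filter clade selection rule. A synthetic-data module
    generates fully self-contained fixtures with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
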