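Package: netscreen
Title: Network-Pharmacology Core-Target Screening for Herbal Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a network-pharmacology screening pipeline for
    identifying core therapeutic targets of multi-herb prescriptions against a
    disease: pooling of herb-ingredient-target tables into a drug target set,
    multi-dataset differential-expression screening with intersection into a
    disease target set, first-neighbour expansion of both seed sets on a
    background protein-protein interactome, intersection-merge of the two
    expanded networks, a two-stage median-adaptive centrality cascade
    (degree, betweenness, closeness) extracting the core target network, and
    hypergeometric over-representation analysis against gene-set collections.
    Ships seeded synthetic-data generators (scale-free interactome, planted
    differential expression, drug-target tables with hub bias, gene sets with
    planted enrichment, two-arm survival data) with ground truth for recovery
    testing, plus Kaplan-Meier, log-rank and 2x2 contingency utilities for
    cohort-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    survival,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cohort.R'
    'diffexpr.R'
    'drugnet.R'
    'enrichment.R'
    'interactome.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
    'topo.R'
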