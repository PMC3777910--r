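Package: regiospec
Title: Regional Specialization of Gene Expression Across Brain Development
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how regional specialization of gene expression changes
    across brain development from spatially resolved expression densities.
    Computes inter-region dissimilarity (1 - Pearson correlation) curves over
    developmental time with quadratic fits, ANOVA and robustness procedures
    (gene subsets, most-variable-gene removal, leave-one-region-out, ontology
    level aggregation); leave-one-gene-out contribution profiles with k-means
    clustering and hypergeometric Gene Ontology enrichment under a two-stage
    false discovery rate correction and GO-hierarchy screening; region-specific
    specialization indices, non-metric multidimensional scaling embeddings with
    Procrustes alignment, and lineage-distance correlation; protein-family
    sequence similarity (global Needleman-Wunsch alignment, BLOSUM50) versus
    spatial expression correlation; and cross-species developmental timeline
    correlation over ortholog pairs. Includes a seeded synthetic-data generator
    with planted temporal, lineage, functional-category and paralog structure
    so every stage can be exercised against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
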