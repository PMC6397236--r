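Package: lncnet
Title: Co-Expression Network Discovery of Disease-Associated lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for finding disease-associated long
    non-coding RNAs (lncRNAs) in microarray expression data: probe
    reannotation with biotype tagging, moderated differential expression,
    weighted gene co-expression network construction (soft-threshold power
    adjacency and topological overlap), module detection and module-trait
    statistics, permutation-based module preservation (Zsummary and median
    rank), a shortest-path-tree hub centrality for ranking intramodular hub
    genes, coding/non-coding network export, and hypergeometric
    over-representation analysis. Ships a synthetic-data generator with
    planted co-expression modules, trait correlations, differential
    expression, lncRNA labels and batch effects so every stage is
    verifiable against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
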