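Package: pcsd
Title: Essential Protein Prediction from Complex Participation and
    Subgraph Density
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks proteins in protein-protein interaction networks by
    predicted essentiality.  An expression-refined network is built from
    per-gene three-sigma activity thresholds, interactions are weighted by
    the edge clustering coefficient times rescaled Pearson co-expression,
    and each protein is scored by its participation degree in protein
    complexes together with the density of its second-order neighborhood
    subgraph weighted by shared Gene Ontology annotations and shared
    complexes.  The two components are combined with a tunable mixing
    parameter.  Includes readers and writers for edge lists, expression
    matrices, complex catalogues and annotation tables, an evaluation
    suite (top-percentage counts, jackknife curves, precision-recall,
    ROC/AUC), and a synthetic data generator with planted structure for
    controlled benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
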