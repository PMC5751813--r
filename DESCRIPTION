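Package: crogo2
Title: Cross-Category Gene Ontology Term Association via Network Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the biological relatedness of Gene Ontology term pairs
    drawn from different GO categories (e.g. biological_process versus
    molecular_function) by diffusing gene-gene association scores over a
    weighted gene co-function network with an iterative-ranking
    (restart-weighted random walk) procedure, measuring a soft set
    difference between the terms' propagated annotation gene sets, and
    down-weighting shallow (near-root) terms.  Builds a directed,
    FDR-filtered cross-category term association network from all pairwise
    scores.  Includes parsers for OBO ontologies, GAF or two-column
    annotation tables and TSV edge lists, a ROC/AUC evaluation protocol
    against gold-standard term pairs, an edge-deletion robustness test,
    and a synthetic benchmark generator with planted cross-category
    modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
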