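Package: ppialign
Title: Global Alignment of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global alignment of two or more protein-protein interaction
    networks. Nodes are characterised by a five-element topological feature
    vector built on the leading eigenvector of the adjacency matrix, sequence
    similarity is taken from min-max normalised BLAST scores, and a combined
    matchset score is maximised by simulated annealing with a Metropolis
    acceptance rule. Alignments are evaluated by protein coverage and by the
    mean (normalised) Shannon entropy of Gene Ontology term annotations
    within matchsets. Includes a synthetic-data generator producing networks
    with known node correspondence, homology tables and annotations, so the
    whole pipeline can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
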