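Package: idmcss
Title: Disease Module Detection by Local Network Adjustment with
    Connectivity and Semantic Similarities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects disease modules in protein-protein interaction (PPI)
    networks by iterative seed expansion on a locally adjusted network.
    Around the current set of disease proteins the method adds likely-missing
    links and removes likely-spurious links, classifying neighbours as strong-
    or weak-linked by a hypergeometric connectivity score and deciding each
    edit by Gene Ontology information-content semantic similarity.  Expansion
    accretes the neighbour with the best combined similarity until a
    disease-related signal (GO terms, differentially expressed genes, or
    pathways) is no longer enriched in the expanded set.  Includes readers for
    edge-list/SIF networks, OBO ontologies, GAF annotations and GMT gene sets,
    evaluation metrics (module closeness, random-subnetwork significance,
    seed-deletion recall), and a planted-module synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
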