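Package: topoicsim
Title: Topological Information-Content Similarity for Gene Ontology Terms and Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic similarity for Gene Ontology (GO) terms and gene products
    based on information-content-weighted shortest and longest paths through
    disjunctive common ancestors of the GO rooted DAG (the TopoICSim measure),
    together with five published comparison measures (IntelliGO, Wang,
    Lord/Resnik, Al-Mubaid, SimGIC) and benchmark statistics (IntraSet/InterSet
    similarity, discriminating power, distance correlation, grouped
    expression-vs-annotation correlation, annotation-length-bias audit).
    Includes parsers for OBO 1.2 ontologies and GAF 2.x annotation files,
    deterministic synthetic fixtures for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
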