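Package: netprop
Title: Multi-Network Integration and Label Propagation for Gene Function
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a weighted composite functional-association network from
    organism-specific source networks (protein interaction, co-expression,
    shared domains and other evidence groups), scores genome-wide gene
    relevance to a query gene list by Gaussian-field label propagation, and
    ranks related genes and attributes with per-edge provenance. Includes
    importers for user-defined organisms (genome tables with synonyms),
    tab-delimited edge lists and expression profiles, a compact binary
    sparse-network store, query-adaptive network weighting by non-negative
    least squares, cross-validated guilt-by-association benchmarking,
    hypergeometric enrichment of result sets, and a deterministic
    planted-partition fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
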