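Package: pathmosaic
Title: Multi-Source Pathway Integration, Network-Based Pathway Extension,
    and Consolidated Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene and metabolite pathway annotations from multiple
    source databases into one collection, predicts additional protein-pathway
    associations from protein-protein interaction network connectivity using
    an upper-tail hypergeometric test with Benjamini-Hochberg correction,
    projects human pathways onto other species through one-to-one orthologs,
    performs over-representation analysis against user-selected backgrounds
    with dual multiple-testing correction and per-source modes, and
    consolidates enrichment results into seven pathway types and fifty-three
    ontology-based categories. Includes a seeded synthetic-data generator
    that emits complete input bundles with planted structure for benchmarking,
    chart-ready reporting tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
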