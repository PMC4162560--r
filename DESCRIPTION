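Package: gecn
Title: Genome-Scale Enzyme Correlation Networks and Co-Expressed Metabolic Routes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds genome-scale enzyme correlation networks (GECN) from
    pathway-genome-database flat files using a product-to-substrate
    enzyme-coupling rule with currency-metabolite exclusion, overlays
    differentially expressed genes (DEGs), induces DEG sub-networks,
    extracts maximal consecutive-step co-expressed metabolic routes
    ("guilt by association"), and compares networks across species keyed
    on EC number. Includes readers and writers for BioCyc-style
    attribute-value files, canonical TSV bundles, DEG tables, binary
    protein-protein interaction lists and Cytoscape SIF, plus a synthetic
    fixture generator with planted routes and transcriptions of published
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    igraph,
    ggplot2,
    generics,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
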