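Package: netpharm
Title: Network-Pharmacology Hub-Gene Screening and Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable implementation of the network-pharmacology inference
    chain that takes a compound's predicted protein targets and a disease
    gene list to consensus hub genes and enrichment evidence. Provides
    gene-list readers with Venn intersection, STRING-dialect
    protein-protein interaction network construction with a confidence
    cutoff, iterative median-threshold centrality screening (degree,
    Brandes betweenness, per-component closeness), MCODE-style dense
    module detection, maximal-clique-centrality (MCC) ranking via
    Bron-Kerbosch enumeration, hypergeometric over-representation
    analysis with Benjamini-Hochberg adjustment over GMT collections,
    two-group differential expression with preranked gene set enrichment
    analysis, seeded synthetic-data generators with recorded ground
    truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
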