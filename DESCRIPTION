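Package: agnet
Title: Prioritization of Biological Processes in Associative Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs associative gene networks around a seed Gene
    Ontology biological process from a typed knowledge graph, ranks
    candidate processes by cross-talk centrality (the fraction of network
    members a candidate is linked to) with hypergeometric over-representation
    p-values and Benjamini-Yekutieli false discovery rate control, clusters
    significant processes by Wang graph-based semantic similarity using the
    Markov Cluster algorithm, and compares significant-process sets across
    several seed networks. Includes a synthetic knowledge-graph and toy
    ontology generator with planted signal so the whole pipeline can be
    exercised and benchmarked offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
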