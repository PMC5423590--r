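Package: coreper
Title: Maximum-Correlation Core/Periphery Partitioning of Binary Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions the actors of a binary (directed or undirected)
    network into a densely connected core and a sparsely connected
    periphery by maximizing the Pearson correlation between an ideal
    core/periphery structure and the observed intra-core and
    intra-periphery ties. The criterion is evaluated in closed form from
    a handful of integer constants, single-actor moves are re-evaluated
    incrementally, and the search is driven by simulated annealing with
    a reciprocal cooling schedule and a multi-restart driver reporting
    attraction rates. Includes an independent vector-based correlation
    oracle with exhaustive search for small networks, a planted-partition
    generator for benchmarking, and readers for dense matrix, edge-list,
    and Pajek network files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
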