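Package: sscd
Title: Active Semi-Supervised Community Detection with Pairwise Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects community structure in undirected, unweighted networks
    guided by pairwise must-link and cannot-link constraints. Constraints seed
    a community skeleton that is expanded greedily using a global node
    similarity obtained by simulating random walks; constraints themselves can
    be acquired actively by querying a noiseless oracle about informative
    nodes (local degree maxima) and uncertain nodes (cluster boundaries).
    Includes partition quality metrics (modularity, label-matched accuracy,
    normalized mutual information), a planted-partition generator for
    benchmarking, an active-versus-random acquisition sweep harness, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
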