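Package: wmilink
Title: Link Prediction in Weighted Networks via Weighted Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Similarity-based link prediction for undirected weighted
    networks. Implements the classical local indices (common neighbours,
    Adamic-Adar, resource allocation) together with their weighted and
    weak-tie-exponent parameterised extensions, and a mutual-information
    score of local structure in which the connection likelihood contributed
    by each common neighbour is estimated from its clustering coefficient
    and fused with link weights (the weighted mutual information family).
    Includes the standard train/probe evaluation protocol (random edge
    splits, precision among the top-L ranked candidate pairs, paired grid
    sweeps over the weak-tie exponent, validation-based exponent selection),
    seeded generators of weighted benchmark graphs with a plantable
    correlation between link weight and endpoint similarity, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
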