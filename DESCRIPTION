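Package: spreadrank
Title: Entropy-Based Identification of Influential Spreader Nodes in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential spreader nodes in undirected, unweighted
    networks with the Entropy Degree Distance Combination (EDDC) centrality,
    which fuses a node's degree, the Shannon entropy of its neighbours' degree
    distribution, and inverse shortest-path weighting. Ships the classical and
    recent baseline centralities (degree, betweenness, closeness, local
    clustering, isolating centrality, local-and-global centrality, K-shell,
    CLGC, ECLGC), a discrete-time Monte-Carlo SIR spreading simulator used as
    ground truth for spreading ability, ranking-evaluation metrics (Kendall
    tau-a, grid-averaged tau, monotonicity, percentage performance gain, top-k
    overlap), seeded random-graph generators (Erdos-Renyi, Barabasi-Albert,
    Watts-Strogatz), a small-world diagnostic, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
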