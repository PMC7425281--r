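Package: btnet
Title: Inference and Validation of Bluetooth Proximity Social Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted social networks from Bluetooth proximity scan
    logs using Laplace-smoothed co-detection rates, and validates them
    against sociometric ground-truth networks by a brute-force search over
    edge-weight thresholds, observation windows (days and scan periods) and
    connection type, scored by classification accuracy or the Matthews
    correlation coefficient. Includes construction of ground-truth networks
    from peer nominations or binary friendship matrices, a structural
    comparison battery (density, gender assortativity, Freeman
    centralization, degree and eigenvector centrality), and a seeded
    simulator of noisy proximity scan logs with planted friendship
    structure, gender homophily and hub nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
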