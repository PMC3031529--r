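Package: nodemotif
Title: Single-Node Motif Detection and Network Fingerprinting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterises every node of a directed or undirected network by
    six local measures (normalised average neighbour degree, neighbour-degree
    coefficient of variation, clustering coefficient, locality index,
    level-two hierarchical clustering coefficient, normalised degree),
    projects the feature vectors to a principal-component plane, estimates a
    probability density with an axis-scaled Gaussian Parzen window, selects
    singular (outlier) nodes by a fully automatic threshold, groups them into
    motif-groups by a deterministic ellipse-overlap clustering, and summarises
    each network as a fingerprint of relative motif-region frequencies.
    Includes seeded generators for ring lattices, Erdos-Renyi,
    Barabasi-Albert and Watts-Strogatz graphs, composite benchmark networks
    with planted outliers, a small-world rewiring time-series, and the
    experiment runners that validate outlier recovery on them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
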