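Package: corridorcut
Title: Cut-Node Ranking for Ecological Corridor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Connectivity analysis of ecological corridor networks modelled as
    patch-adjacency graphs. Detects cut nodes (articulation points), simulates
    their removal to quantify fragmentation (additional component count and
    second-size), computes component-normalized betweenness centrality and
    minimum boundary distance to protected sites, and combines the metrics into
    a single priority ranking through strictly-less percentile scores. Includes
    a seeded generator of corridor-like synthetic landscapes with ground-truth
    labels, a lightweight planar geometry front end (polygon overlay, rook and
    queen contiguity, boundary distances, GeoJSON), and a command-line driver
    for the full ranking pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
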