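Package: ddlayout
Title: Data-Driven Layouts of Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Produces data-driven layouts (DDLs) of biological networks by
    positioning nodes according to dimension reduction of their associated
    numerical profiles (typically gene expression) instead of graph topology
    alone. Implements missing-data principal component analysis by
    alternating least squares, two-dimensional elastic-map principal
    manifolds, optional double-centering and graph-Laplacian network
    smoothing of the data matrix, layout post-processing (overlap jitter,
    outlier pull-in, neighbour-mean placement of filtered nodes), continuous
    morphing between two layouts, rigid Procrustes alignment by rotation and
    mirroring, and a distance-preservation quality criterion based on
    farthest-point-sampled representative pairs. Reads and writes SIF, edge
    list, GraphML, XGMML and tab-separated formats, and ships a command-line
    driver chaining the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
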