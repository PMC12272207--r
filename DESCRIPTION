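Package: enct
Title: Edge-Centric Network Control Theory for Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms weighted structural connectomes into edge-centric
    (line-graph) networks via the incidence matrix, computes average and
    modal controllability at the node and edge level, solves the
    minimum-energy optimal control problem for activating edge patterns,
    and provides the accompanying inferential machinery: degree- and
    strength-preserving rewiring null models with nonparametric p-values
    and FDR correction, connectome-based predictive modeling (CPM) of
    phenotypes from edge features, and a synthetic-connectome generator
    for testing and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
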