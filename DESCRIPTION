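Package: tjquant
Title: Quantification of Tight-Junction Fragmentation in Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the integrity of epithelial tight junctions from
    immunofluorescence images of junction markers such as ZO-1. Image stacks are
    collapsed by maximum-intensity projection, thin bright membrane lines are
    enhanced by the smallest eigenvalue of the Hessian tensor, binarized and
    skeletonized; junction points where three or more branches meet are detected
    by a binary hit-or-miss operation and subtracted, and the remaining skeleton
    branches are counted and measured as continuous membrane segments. Segment
    length histograms and the abundance of large segments are compared between
    conditions with the Mann-Whitney rank-sum test. Includes a synthetic
    epithelial-monolayer image generator (Voronoi cell geometry, controllable
    network fragmentation, optical blur and sensor noise) with full ground truth,
    and relative gene-expression quantification from qPCR cycle-threshold tables
    by the comparative 2^-ddCt method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
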