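Package: neuromast
Title: Quantitative Analysis of Lateral-Line Neuromast Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the synaptic microcircuit of the zebrafish
    lateral-line neuromast from serial-section electron-microscopy
    annotations.  Computes membrane contact areas between traced cell
    contours under a proximity-with-occlusion rule, classifies afferent and
    efferent axonal terminals, assigns ribbon-synapse partners, and derives
    polarity-specificity, redundancy, dominance, and sibling-exclusivity
    statistics for wild-type, trilobite, and Notch-overexpression specimens.
    Includes a CART classifier for post-mitotic hair-cell age and a
    synthetic-connectome generator with a planted ground-truth ledger so
    every pipeline stage can be tested without electron-microscopy volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
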