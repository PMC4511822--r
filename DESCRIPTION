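Package: neuroconn
Title: Multimodal Brain Connectivity Matrices, Graph Metrics and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs anatomical, structural, functional, effective and PET
    connectivity matrices from preprocessed neuroimaging inputs (parcellation
    label volumes, tractography streamlines, ROI time series, morphometry
    tables); performs subject-stack matrix algebra (mean, robustness, combined,
    hybrid structural-functional matrices, direct/mediated decomposition with
    mediated-path search); computes graph-theory metrics with random-graph
    normalization; runs between-group statistics with covariate regression; and
    renders matrix, connectogram and 3D-graph views. Ships a synthetic-data
    generator with planted ground truth so the full pipeline is testable
    without any imaging dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
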