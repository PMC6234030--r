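Package: glomquant
Title: Quantification of Glomerular Connectomes from Polyadic Synapse Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn dense electron-microscopy synapse annotations of an
    olfactory glomerulus into quantitative circuit descriptions. Polyadic
    synapses (one presynaptic T-bar ribbon with several postsynaptic
    densities) are expanded into directed contacts, filtered to the bodies
    with sufficient partnerships, and assembled into a cell-by-cell contact
    matrix. From the matrix the package derives per-cell synaptic statistics,
    connection-strength distributions, class-level synaptic flow networks,
    and reciprocity motifs between cell pairs and cell classes. A
    density-based segmentation of 3D synapse point clouds demarcates
    glomerulus-like territories for region-of-interest assignment, and a
    calibrated synthetic glomerulus generator provides ground-truth datasets
    for testing every pipeline stage without an EM volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    readxl,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
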