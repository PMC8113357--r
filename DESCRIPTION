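Package: patchseqr
Title: Multimodal Patch-Seq Analysis of Cortical Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for multimodal Patch-seq data from
    cortical neurons. Extracts 29 electrophysiological features from
    current-clamp sweep sets (passive properties, rheobase, action
    potential shape, adaptation, sag, rebound, burstiness), maps cells
    to reference transcriptomic types by nearest-centroid Pearson
    correlation with gene-bootstrap confidence and consensus across
    reference atlases, computes neuron morphometrics and normalized
    cortical-depth profiles from SWC reconstructions, links gene
    expression to electrophysiological phenotype with sparse
    reduced-rank regression, builds morpho-electric representations for
    embedding and k-nearest-neighbour family classification, and
    quantifies within-type phenotypic variability. Includes synthetic
    generators for all three modalities with known ground truth so the
    full pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    igraph,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
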