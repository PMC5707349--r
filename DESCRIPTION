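Package: popclock
Title: Differentiation-Time Inference for Single Cells from Matched
    Cell-Population RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers a real-scale differentiation time for single-cell
    transcriptomes by fitting a partial-least-squares time model on a
    matched bulk (cell-population) RNA-seq time course and transferring
    it to single cells. Includes a sampling-saturation analysis that
    quantifies how many single cells are needed to capture intercellular
    heterogeneity against the bulk reference, synthetic-data generators
    (mixtures, read-depth downsampling, discrete subtypes with a rare
    population, expanding two-population time courses, planted-timer
    trajectories), minimum-cost-flow subnetwork inference linking
    bulk-only signaling genes to single-cell timer genes, connection
    specificity index co-expression networks, and enrichment machinery
    (hypergeometric tests, GSEA, rank-product differential expression,
    permutation interaction tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    limma,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
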