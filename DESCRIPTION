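Package: embryomap
Title: Reference-Based Projection and Lineage Annotation for Early Embryo
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds an integrated multi-batch single-cell RNA-seq reference
    atlas of early embryogenesis with recorded correction metadata
    (rescaling factors, grand centers, singular vectors, batch-correction
    vectors, embedding models), projects query cells onto the frozen
    reference without perturbing it, and predicts per-cell lineage
    identities with explicit abstention labels (ambiguous, nonrelated,
    nb_failed). Includes mutual-nearest-neighbour batch correction with
    kernel-smoothed, variance-adjusted, orthogonalized corrections,
    subsampled query MNN pairing with correlation filtering, per-lineage
    RBF-SVM classifiers gated by probability and MNN support, milo-style
    neighbourhood aggregation for sparse droplet data, Wilcoxon marker
    detection, module scores, Stouffer p-value combination, consensus
    differential-expression filtering, and a synthetic-data generator
    emulating the statistical structure of multi-batch embryo atlases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    uwot,
    igraph,
    e1071,
    scran,
    methods,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
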