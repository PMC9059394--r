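Package: cccdiff
Title: Differential Cell-Cell Communication Analysis Between Sample Groups
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers cell-cell communication from annotated, log-normalized
    single-cell or single-nucleus expression data using a mass-action
    ligand-receptor model with heteromeric complexes and cofactors, assesses
    significance by cell-type label permutation, aggregates interactions to
    signaling-pathway scores and information flow, and compares two sample
    groups by both a merged "global" design and a per-sample pseudo-bulk
    design with Wilcoxon tests, FDR control, PCA and subsampling robustness.
    Also provides latent communication-pattern detection by non-negative
    matrix factorization with consensus-based rank selection, downstream
    overrepresentation / gene-list overlap / preranked gene-set enrichment
    statistics, spatial ligand-receptor co-expression tests, and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    cluster,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, CellBiology, DifferentialExpression,
    Software
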