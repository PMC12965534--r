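Package: scStatePerturb
Title: Rank-Encoding Transformers and In Silico Perturbation for
    Two-State Single-Cell Corpora
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale discovery of disease-state driver genes
    from single-cell RNA-seq counts. Each cell's transcriptome is encoded
    as a rank-value gene-token sequence, a small transformer encoder is
    trained (optionally with masked-gene pretraining) to classify cells
    between two conditions, and candidate drivers are identified by in
    silico deletion or overexpression of gene tokens, scoring each gene by
    the mean cosine shift of the perturbed cell embeddings toward a goal
    state, with Wilcoxon rank-sum significance and Benjamini-Hochberg FDR
    control. A permutation procedure over random equal splits of control
    cells estimates the natural-fluctuation zone for per-gene log2 fold
    changes, against which observed disease-versus-control changes are
    calibrated. A negative-binomial corpus simulator with planted driver
    genes makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
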