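Package: blockSig
Title: Multiblock Sparse PLS-DA with Stability-Based Signature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative classification of binary tissue phenotypes from
    multiple aligned omics blocks (e.g. transcriptomics, proteomics,
    peptidomics). Implements single-block and multiblock (design-matrix
    coupled) sparse partial least squares discriminant analysis with
    soft-thresholded loadings, balanced-error-rate cross-validation tuning
    over piecewise feature grids, stability-based feature selection by
    stratified resampling with loading-weight aggregation, and the
    surrounding statistics: missingness filtering and k-nearest-neighbour
    imputation, differential expression, Pearson component-trait
    correlation, hypergeometric gene-set overrepresentation with
    Benjamini-Hochberg adjustment, preranked gene-set enrichment analysis,
    and signature validation with penalized logistic regression, RBF
    support vector machines and decision trees under stratified repeated
    cross-validation. Includes a synthetic multiomics generator with
    planted latent class structure for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    fgsea,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
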