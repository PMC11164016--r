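Package: fmtomics
Title: Multi-Omics Analysis of Fecal Microbiota Transplantation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taxon- and subcommunity-level analysis of randomized
    fecal microbiota transplantation (FMT) trials with paired serum
    metabolomics. Implements compositional preprocessing of amplicon
    sequence variant (ASV) tables (read-depth and relative-abundance
    filters, genus agglomeration), centered log-ratio transforms and
    Aitchison distances, permutational multivariate ANOVA, latent
    Dirichlet allocation of microbial subcommunities with data-driven
    topic-number selection, a zero-sum constrained log-ratio lasso for
    binary outcomes with repeated cross-validation stability selection,
    anchor-sample median-ratio batch normalization and quality control of
    untargeted metabolomics, stability-selected logistic lasso and sparse
    partial least squares discriminant analysis of outcomes, an ASV-level
    donor-engraftment similarity index, and cross-omics Spearman
    correlation maps. A synthetic-trial generator with known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
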