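Package: rpstack
Title: Random-Projection Stacked Learning for Transcriptome Subtype Classification
Version: 0.1.0
Authors@R: person("rpstack", "maintainers", email = "maintainers@rpstack.dev", role = c("aut", "cre"))
Description: Classifies bulk RNA-seq samples into molecular subtypes by fusing
    multiple independent Gaussian random projections of the expression matrix
    and stacking a heterogeneous zoo of base classifiers (nearest neighbours,
    random forests, extremely randomised trees, and three gradient-boosting
    variants) under a multi-layer-perceptron meta-learner trained on
    out-of-fold base predictions. Includes a seeded synthetic bulk RNA-seq
    generator with planted differential expression and correlated gene blocks,
    TPM normalisation and expression matrix input/output, distance-preservation
    diagnostics for the projections, a repeated stratified cross-validation
    benchmark harness with accuracy/F1/MCC/AUC and paired signed-rank
    comparisons, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    FNN,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
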