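Package: glycanmotifs
Title: Lectin-Binding Motif Discovery from Glycan Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies candidate lectin-binding motifs from glycan microarray
    experiments and trains interpretable classifiers of glycan binding.
    Glycans written in CFG linear nomenclature are parsed into rooted labelled
    trees and augmented with restricted-linkage nodes that mark unoccupied but
    chemically capable attachment positions, so that terminal motifs can be
    distinguished from internal ones. Positive binders are called from
    relative fluorescence units by a robust median-absolute-deviation outlier
    rule; candidate motifs are mined as frequent subtrees, reduced by
    minimum-redundancy maximum-relevance selection and L1-regularised weighted
    logistic regression with collinearity pruning, and assembled into an
    L2-regularised logistic model that predicts binding probability for
    arbitrary glycans. A synthetic-array generator with planted motifs
    supports end-to-end validation without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
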