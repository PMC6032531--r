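Package: tgpredict
Title: Gene-Expression-Signature Model of Response to Tripterysium
    Glycosides in Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and evaluation of transcriptomic biomarker
    signatures that predict whether rheumatoid-arthritis patients
    respond to Tripterysium glycosides (TG) tablets.  Implements the
    random-variance-model moderated t-test for small two-group
    microarray cohorts, median-filtered interaction-network construction
    with degree/closeness/betweenness candidate-gene selection,
    hypergeometric gene-set over-representation with dual Bonferroni and
    Benjamini-Hochberg correction, a one-component partial-least-squares
    patient score with ROC-based threshold selection, repeated
    stratified k-fold cross-validation and DeLong AUC comparison, and
    comparative-CT (2^-ddCt) quantification of validation-cohort qPCR
    data.  A synthetic-cohort generator with planted differential
    expression and planted network hubs makes the full pipeline testable
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
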