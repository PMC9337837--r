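Package: cinrules
Title: Feature Ranking, Incremental Feature Selection and Rule Induction
    for Single-Cell Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies single cells into regions of origin from
    RPKM-like expression profiles. Implements minimum-redundancy
    maximum-relevance (mRMR) feature ranking on a three-state
    discretization, incremental feature selection (IFS) with pluggable
    learners (a 100-tree ensemble and a RIPPER-style decision-list rule
    inducer), the covariance-form multiclass Matthews correlation
    coefficient, stratified and repeated cross-validation, a synthetic
    zero-inflated expression-matrix generator with planted marker genes,
    text formats for expression matrices, labels and threshold rulesets,
    and an end-to-end reproducible pipeline. Ships a reference decision
    list of 22 threshold rules for caudal and medial ganglionic eminence
    interneuron progenitors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
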