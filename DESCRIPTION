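Package: sigpanel
Title: Serum Protein Signature Discovery from Antibody Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed recombinant antibody
    microarray serum profiles for diagnostic biomarker panel discovery.
    Implements spot-level replicate aggregation with a coefficient-of-variation
    dismissal rule, two-step normalization (per-round subtract-group-mean and
    per-array scaling from low-CV reference antibodies), differential
    expression statistics with Benjamini-Hochberg q-values, p-value-filtered
    principal component projections, and a support-vector-machine backward
    elimination engine that ranks antibodies by Kullback-Leibler
    classification error, scores them by elimination endurance across
    repeated stratified splits, and evaluates frozen consensus-panel models
    on independent test sets (AUC, sensitivity, specificity, predictive
    values). A synthetic cohort generator with planted group effects, batch
    shifts and replicate noise supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    e1071,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
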