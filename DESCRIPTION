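Package: cascadeWx
Title: Cascaded Wx Prognosis-Related Feature Selection for Survival Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survival-aware gene selection for bulk transcriptome cohorts via
    the cascaded Wx framework: samples are stratified into high- and low-risk
    groups at successive survival cutoffs, a softmax classifier is trained at
    each step, and features are reduced quarter-wise using the discriminating
    power of the trained weights. Includes a Faraggi-Simon feed-forward
    proportional-hazards survival model fitted by negative log partial
    likelihood, Harrell's concordance index, log-rank and Kaplan-Meier
    utilities, stratified cross-validation with rank merging across folds,
    and a synthetic survival-transcriptome cohort generator with known causal
    genes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
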