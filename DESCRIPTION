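Package: tissuescope
Title: MTI-Supported Tissue Discovery from Paired miRNA and mRNA
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies the tissue subsets in which a microRNA and its
    experimentally validated target genes are strongly negatively
    correlated ("MTI-supported tissues"). A weighted loss combining the
    mean miRNA-target correlation with the proportion of negative
    correlations is minimized over randomly sampled (or exhaustively
    enumerated) tissue subsets across a range of subset sizes; tissues
    are then ranked by their occurrence among the per-size best subsets.
    Includes expression-matrix and interaction-catalog readers, detection
    cutoff preprocessing, organ-level extension of selected subsets,
    permutation-based evaluation, correlation-density diagnostics, and a
    synthetic data generator with planted tissue-restricted
    down-regulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
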