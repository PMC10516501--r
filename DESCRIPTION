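Package: mitopq
Title: Quantification of Mitochondrial Protein Solubility from
    Spike-In-Normalized Isobaric-Labeling Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring mitochondrial proteostasis from
    detergent-fractionated, tandem-mass-tag (TMT) labeled proteomics
    experiments. Reads MaxQuant-dialect protein-group tables, computes
    per-channel scaling factors from a bacterial spike-in protein (Ag85A),
    performs left-censored (QRILC-style) imputation for batch-level
    missingness, derives per-protein percent-insoluble values from paired
    soluble/insoluble fractions, summarizes aggregation indices over
    functional protein groups, computes stress-recovery rates over a
    treatment/recovery time course, and partitions differential-expression
    gene sets into transcription-factor dependency classes. A synthetic-data
    generator with known ground truth supports end-to-end validation of
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
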