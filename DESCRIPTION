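Package: phylotrax
Title: Evolutionary Transcriptomics Indices and Developmental Shape Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Expression-weighted evolutionary indices for developmental
    transcriptomes: the transcriptome age index (TAI), transcriptome
    specificity index (TSI) and transcriptome divergence index (TDI), with
    bootstrap uncertainty, nonparametric permutation tests for flat-line,
    reductive-hourglass and pairwise profile shapes, per-gene contribution
    (pTAI) analysis with elbow-based driver selection, orthogroup-level
    cross-species transcriptome distances (Pearson, Spearman, Manhattan,
    Jensen-Shannon), and a synthetic-data generator that emulates
    stage-structured RNA-seq expression with age-structured genes for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
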