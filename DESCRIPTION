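Package: oncolines
Title: Transcriptome Characterization and Tumor-Fidelity Scoring of Cancer
    Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-wide characterization of cancer cell
    line panels and for scoring how faithfully each cell line represents
    its disease-matched tumor cohort. Implements nTPM normalization
    (protein-coding TPM rescaling followed by trimmed-mean-of-M-values
    scaling against a median reference column), classification of genes by
    expression distribution and disease specificity (enriched,
    group-enriched, enhanced, low-specificity, not detected),
    correlation- and preranked-GSEA-based prioritization of cell lines
    against tumor cohorts with rank integration, consensus linear-model
    pathway activity and permutation-based cytokine activity inference,
    and a synthetic-data generator that plants known specificity
    categories, best-matching cell lines, and pathway activities so every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    DESeq2
Config/testthat/edition: 3
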