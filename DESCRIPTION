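Package: csfShift
Title: Quantifying Cerebrospinal-Fluid-Induced State Shifts in Glioblastoma Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for studying how culture in human
    cerebrospinal fluid (CSF) shifts patient-derived glioblastoma cells toward
    quiescent, mesenchymal-like, therapy-resistant transcriptional states.
    Provides single-cell quality control (prefiltering, four-criterion outlier
    tagging, per-line condition balancing), log-normalization and
    highly-variable-gene selection, expression-bin-matched module scoring for
    cell-cycle, quiescence and the four glioblastoma meta-modules
    (AC/MES/NPC/OPC), two-axis cell-state projection and quadrant
    classification, balanced-downsampled Wilcoxon differential expression with
    Bonferroni correction, preranked gene-set enrichment analysis with the
    weighted statistic and gene-set permutations, plate-based cytotoxicity and
    four-parameter logistic dose-response analysis, comparative-CT qPCR
    quantitation, and multielectrode-array spike-train neurotoxicity metrics.
    A synthetic-data generator plants known condition effects so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
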