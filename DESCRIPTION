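Package: scnodule
Title: Single-Cell Transcriptomic Analysis of Lung Nodule Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying lung adenocarcinoma progression across
    radiological stages (normal tissue, pure ground-glass nodule, solid
    nodule) from droplet single-cell RNA-seq UMI counts. Implements cell
    quality control (detected-gene, mitochondrial-fraction and doublet
    filters), expression-derived relative copy-number profiling by
    reference-centered sliding-window smoothing along genomic gene order,
    malignant-cell classification by correlation of per-cell CNV profiles
    to a high-burden clone archetype, marker-set cell-type scoring,
    stage-wise composition summaries, Wilcoxon rank-sum differential
    expression with Benjamini-Hochberg control, and permutation-based
    ligand-receptor interaction scoring between cell types. A synthetic
    cohort generator with planted CNV clones, QC artifacts and
    ligand-receptor signal provides ground truth for every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    methods,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
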