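# scnodule

Single-cell transcriptomic analysis of lung adenocarcinoma progression
across radiological stages — normal lung tissue, pure ground-glass nodule
(pGGN, the indolent early lesion), and solid nodule (SN, the relatively
advanced lesion).

The package is aimed at computational biologists who want a compact,
fully tested implementation of the analytical core of a three-stage
droplet scRNA-seq tumor study, exercisable end to end on synthetic
cohorts with planted ground truth:

- **Cell QC** — remove cells with `< 200` detected genes or `> 10%`
  mitochondrial UMI (low quality), and cells with `> 5000` detected genes
  (putative doublets). Boundaries are strict: cells exactly at a
  threshold are kept.
- **Expression-derived CNV profiles** — per sample, stromal/immune cells
  are a copy-neutral reference; genes with reference mean count `< 0.1`
  are dropped; epithelial cells' log-normalized expression is centered on
  the reference mean, clipped to ±3, smoothed by a 101-gene moving
  average along genomic gene order (truncated at chromosome boundaries),
  and re-centered on the per-cell median.
- **Malignant-cell calling** — per cell, the CNV score is the mean square
  of its profile; the top 5% of cells by score form the malignant clone
  archetype; cells whose profile has Pearson *r* > 0.3 with the archetype
  mean profile are called malignant.
- **Stage analysis** — marker-set cell-type scoring (mean z-scored
  marker expression, argmax assignment), composition by stage, and DEG
  calling by two-sided Wilcoxon rank-sum with Benjamini–Hochberg
  control, kept at `|avg_logFC| ≥ 0.25` and adjusted `p ≤ 0.05`, where
  `avg_logFC = ln(mean(expm1(norm_A)) + 1) − ln(mean(expm1(norm_B)) + 1)`.
  Stage-dependent DEGs move in the same direction in both adjacent
  contrasts (normal → pGGN and pGGN → SN).
- **Ligand–receptor interactions** — per stage, the interaction mean of a
  pair between a sender and receiver cell type is the average of the
  ligand's sender-cluster mean and the receptor's receiver-cluster mean;
  significance comes from 1000 global cell-type label shuffles,
  `p = (1 + #{permuted ≥ observed}) / (1 + 1000)`, with a 10%
  expressing-cell fraction filter.
- **Synthetic cohorts** — `sim_config()`/`generate_cohort()` draw UMI
  counts gene-wise from a negative binomial with log-normal baselines and
  library factors, planting cell-type markers, one CNV clone per tumor
  sample (contiguous gain/loss segments), QC artifacts, and stage-biased
  ligand–receptor co-expression, all recorded in a truth table.

Everything is tidyverse-native: result tables are tibbles, fitted objects
have `tidy()`/`glance()` methods, each result type has an `autoplot()`.

## Worked example

```r
library(scnodule)

cfg <- sim_config(
  n_genes = 2000, n_chromosomes = 8,
  n_samples = c(normal = 1, pGGN = 1, SN = 1),
  cell_counts = list(
    normal = c(epithelial = 200, T_cell = 150, myeloid = 100),
    pGGN   = c(epithelial = 200, T_cell = 150, myeloid = 100),
    SN     = c(epithelial = 200, T_cell = 150, myeloid = 100)),
  cnv_segment_genes = 150,
  artifact_counts = c(low_gene = 3, high_mito = 3, doublet = 0),
  seed = 1)
sim <- generate_cohort(cfg)
sim$cohort
#> <cohort> 2000 genes x 1356 cells
#>   samples: normal1, pGGN1, SN1
#>   stages:  normal=452, pGGN=452, SN=452

qc <- apply_qc_filters(sim$cohort)
qc$removed[, c("barcode", "n_genes_detected", "mito_frac", "reason")]
#> # A tibble: 6 x 4
#>   barcode                  n_genes_detected mito_frac reason
#> 1 normal1_art_low_gene001                31    0      low_gene
#> 2 pGGN1_art_low_gene002                  39    0      low_gene
#> 3 SN1_art_low_gene003                    39    0.0137 low_gene
#> 4 normal1_art_high_mito004              908    0.309  high_mito
#> 5 pGGN1_art_high_mito005               1041    0.277  high_mito
#> 6 SN1_art_high_mito006                  736    0.291  high_mito
```

The six planted artifact cells — and only those — fail QC, each with the
reason that matches how it was planted. CNV profiling and malignancy
calling then recover the planted clones; the configured malignant
fractions were 0.2 (pGGN) and 0.6 (SN):

```r
mal <- run_malignancy_per_sample(infer_cnv_per_sample(qc$kept))
glance(mal)
#> # A tibble: 2 x 5
#>   sample stage n_cells n_malignant malignant_fraction
#> 1 SN1    SN        200         131              0.655
#> 2 pGGN1  pGGN      200          57              0.285
```

Differential expression between the tumor stages on epithelial cells:

```r
norm <- normalize_log(qc$kept)
epi <- function(st) which(qc$kept$cells$stage == st &
                          qc$kept$cells$cell_type == "epithelial")
deg <- wilcoxon_deg(norm, epi("SN"), epi("pGGN"),
                    contrast = "SN_vs_pGGN", cell_type = "epithelial")
nrow(deg)   # 51 genes pass |logFC| >= 0.25 & BH p <= 0.05 (13 up, 38 down)
```

The 51 significant genes are dominated by the clone segment genes that
differ between the two samples' planted gains and losses. Plots:
`autoplot(composition_by_stage(qc$kept$cells))`,
`autoplot(mal)`, `autoplot(infer_cnv(qc$kept, "SN1"))`.

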