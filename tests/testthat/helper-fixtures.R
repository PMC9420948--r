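# Shared fixtures and independent oracles for the test suite.

# A small hand-checkable cohort: 5 genes (last one mitochondrial) x 4 cells.
tiny_cohort <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 5, 1, 2, 1),
    j = c(1, 1, 1, 1, 2, 2, 4),
    x = c(40, 30, 20, 10, 5, 5, 7),
    dims = c(5, 4))
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chrM"),
    start = c(0, 10000, 20000, 0, 0),
    is_mito = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  cells <- tibble::tibble(
    barcode = paste0("c", 1:4),
    sample = "s1", stage = "normal")
  cohort(counts, genes, cells)
}

# Small simulated cohort used across modules.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(
    n_genes = 600, n_chromosomes = 3,
    n_samples = c(normal = 1, pGGN = 1, SN = 1),
    cell_counts = list(
      normal = c(epithelial = 60, T_cell = 40, myeloid = 30),
      pGGN   = c(epithelial = 60, T_cell = 40, myeloid = 30),
      SN     = c(epithelial = 60, T_cell = 40, myeloid = 30)),
    cnv_segments = "none", seed = seed, ...)
  generate_cohort(cfg)
}

# Naive O(n * w) double-loop moving average with chromosome truncation:
# the independent oracle for smooth_sliding_window().
oracle_smooth <- function(centered, chrom, window, recenter = TRUE) {
  centered <- as.matrix(centered)
  g <- nrow(centered)
  h <- (window - 1) / 2
  out <- centered
  for (j in seq_len(ncol(centered))) {
    for (i in seq_len(g)) {
      idx <- which(chrom == chrom[i] & abs(seq_len(g) - i) <= h)
      out[i, j] <- mean(centered[idx, j])
    }
  }
  if (recenter) out <- sweep(out, 2, apply(out, 2, stats::median))
  out
}

# Independent brute-force label-permutation p-value: plain subsetting and
# mean(), no matrix products; same RNG stream as the package engine.
oracle_perm_p <- function(norm, ligand, receptor, labels, sender, receiver,
                          n_perm, seed) {
  m <- as.matrix(norm)
  obs_of <- function(lab) {
    (mean(m[ligand, lab == sender]) + mean(m[receptor, lab == receiver])) / 2
  }
  obs <- obs_of(labels)
  set.seed(seed)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    lab <- labels[sample.int(length(labels))]
    if (obs_of(lab) >= obs) exceed <- exceed + 1
  }
  (1 + exceed) / (1 + n_perm)
}

# Sensitivity/specificity of malignancy calls against planted truth.
malignancy_confusion <- function(mal, truth) {
  tt <- dplyr::left_join(tidy(mal),
                         truth$cells[, c("barcode", "is_malignant")],
                         by = "barcode", suffix = c("", "_true"))
  list(sensitivity = sum(tt$is_malignant & tt$is_malignant_true) /
         sum(tt$is_malignant_true),
       specificity = sum(!tt$is_malignant & !tt$is_malignant_true) /
         sum(!tt$is_malignant_true))
}

# Tumor cohort with one gain + one loss clone per sample (or the matched
# copy-neutral null when `null = TRUE`): the malignancy-recovery conditions.
clone_cohort_config <- function(seed, null = FALSE, epithelial = 800) {
  sim_config(
    n_genes = 4000, n_chromosomes = 8,
    n_samples = c(normal = 0, pGGN = 2, SN = 2),
    cell_counts = list(
      pGGN = c(epithelial = epithelial, T_cell = 300, NK_cell = 100,
               myeloid = 200),
      SN   = c(epithelial = epithelial, T_cell = 300, NK_cell = 100,
               myeloid = 200)),
    malignant_fraction = c(pGGN = 0.2, SN = 0.6),
    cnv_segments = "auto",
    cnv_gain_ratio = if (null) 1 else 1.5,
    cnv_loss_ratio = if (null) 1 else 0.5,
    cnv_segment_genes = 250,
    seed = seed)
}
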