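#' Configure a synthetic single-cell cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults emulate the statistical structure of a three-stage lung
#' adenocarcinoma cohort: four samples each of normal tissue, pure
#' ground-glass nodule (pGGN) and solid nodule (SN); a mixture of epithelial,
#' immune and stromal cell types whose proportions are set per stage; UMI
#' counts drawn gene-wise from a negative binomial with a log-normal
#' per-gene baseline and a log-normal per-cell library-size factor; one
#' malignant clone per tumor sample carrying contiguous copy-gain and
#' copy-loss segments; and optional QC artifacts (low-gene cells, high-mito
#' cells, doublets) and stage-biased ligand-receptor co-expression.
#'
#' The expected count of gene g in cell c is
#' `baseline_mean[g] * marker_boost^[g marker of c's type] *
#'  copy_ratio[g, clone(c)] * lr_boost^[planted L-R gene for c] *
#'  library_factor[c]`,
#' with no renormalization after boosts, so planted effects change both the
#' gene's share and the cell's total depth, as a real amplification would.
#'
#' @param n_genes Total number of simulated genes.
#' @param n_chromosomes Number of chromosomes the genes are laid out on.
#' @param genes_per_chromosome Integer vector summing to `n_genes`;
#'   `NULL` splits genes as evenly as possible.
#' @param n_samples Named integer vector: samples per stage.
#' @param cell_counts Named list `stage -> named integer vector
#'   (cell_type -> count)` giving cells per stage (split evenly across that
#'   stage's samples); `NULL` uses a default mixture that shifts plausibly
#'   across stages.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma Parameters of the
#'   log-normal distribution of relative per-gene baseline expression.
#' @param nb_dispersion Negative-binomial size (inverse-dispersion) shared by
#'   all genes; variance is `mu + mu^2 / nb_dispersion`.
#' @param library_size_mean Expected UMI total of an un-boosted cell.
#' @param library_size_sigma Log-scale SD of the per-cell library factor.
#' @param marker_boost Fold-change applied to a cell type's marker genes in
#'   cells of that type.
#' @param markers_per_type Number of dedicated marker genes per cell type.
#' @param cnv_segments Either `"auto"` (default: one gain + one loss segment
#'   per tumor sample, placed on distinct chromosome slots), `"none"`, or a
#'   named list `sample -> data.frame(chromosome, start_gene_index,
#'   end_gene_index, copy_ratio)` with gene indices 1-based *within* the
#'   chromosome.
#' @param cnv_gain_ratio,cnv_loss_ratio,cnv_segment_genes Copy ratios and
#'   segment length (in genes) used by the `"auto"` clone layout.
#' @param malignant_fraction Named vector: fraction of epithelial cells that
#'   are malignant, per tumor stage.
#' @param mito_gene_count Number of mitochondrial genes (placed at the end of
#'   the last chromosome and flagged `is_mito`).
#' @param mito_frac_target Expected mitochondrial UMI fraction of a clean
#'   cell.
#' @param artifact_counts Named vector `c(low_gene=, high_mito=, doublet=)`:
#'   number of planted QC-artifact cells of each kind.
#' @param low_gene_pool Number of genes a low-gene artifact cell can express.
#' @param high_mito_frac Expected mito fraction of a high-mito artifact.
#' @param doublet_boost Initial library multiplier for the two parent cells
#'   of a doublet artifact; escalated until the doublet exceeds
#'   `doublet_min_genes` detected genes.
#' @param doublet_min_genes Detected-gene count a planted doublet must
#'   exceed (the QC doublet rule it is meant to trip).
#' @param lr_pairs_planted `NULL`, or a data frame with columns
#'   `ligand_gene`, `receptor_gene`, `sender_type`, `receiver_type`,
#'   `stage`: in the named stage, the ligand is boosted in sender-type cells
#'   and the receptor in receiver-type cells by `lr_boost`.
#' @param lr_boost Fold-change applied to planted ligand/receptor genes.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   byte-for-byte.
#'
#' @return A `sim_config` list, validated.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_genes = 4000,
                       n_chromosomes = 8,
                       genes_per_chromosome = NULL,
                       n_samples = c(normal = 4, pGGN = 4, SN = 4),
                       cell_counts = NULL,
                       baseline_mean_log_mu = 0,
                       baseline_mean_log_sigma = 1,
                       nb_dispersion = 2,
                       library_size_mean = 2000,
                       library_size_sigma = 0.3,
                       marker_boost = 8,
                       markers_per_type = 10,
                       cnv_segments = "auto",
                       cnv_gain_ratio = 1.5,
                       cnv_loss_ratio = 0.5,
                       cnv_segment_genes = 250,
                       malignant_fraction = c(pGGN = 0.2, SN = 0.6),
                       mito_gene_count = 10,
                       mito_frac_target = 0.03,
                       artifact_counts = c(low_gene = 0, high_mito = 0,
                                           doublet = 0),
                       low_gene_pool = 100,
                       high_mito_frac = 0.25,
                       doublet_boost = 4,
                       doublet_min_genes = 5000,
                       lr_pairs_planted = NULL,
                       lr_boost = 4,
                       seed = 1L) {
  if (is.null(cell_counts)) {
    cell_counts <- list(
      normal = c(epithelial = 400, T_cell = 320, NK_cell = 140, B_cell = 60,
                 myeloid = 200, fibroblast = 40, endothelial = 40),
      pGGN   = c(epithelial = 400, T_cell = 340, NK_cell = 100, B_cell = 80,
                 myeloid = 180, fibroblast = 50, endothelial = 50),
      SN     = c(epithelial = 400, T_cell = 280, NK_cell = 60, B_cell = 120,
                 myeloid = 240, fibroblast = 60, endothelial = 60))
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = genes_per_chromosome,
    n_samples = n_samples,
    cell_counts = cell_counts,
    baseline_mean_log_mu = baseline_mean_log_mu,
    baseline_mean_log_sigma = baseline_mean_log_sigma,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    library_size_sigma = library_size_sigma,
    marker_boost = marker_boost,
    markers_per_type = as.integer(markers_per_type),
    cnv_segments = cnv_segments,
    cnv_gain_ratio = cnv_gain_ratio,
    cnv_loss_ratio = cnv_loss_ratio,
    cnv_segment_genes = as.integer(cnv_segment_genes),
    malignant_fraction = malignant_fraction,
    mito_gene_count = as.integer(mito_gene_count),
    mito_frac_target = mito_frac_target,
    artifact_counts = artifact_counts,
    low_gene_pool = as.integer(low_gene_pool),
    high_mito_frac = high_mito_frac,
    doublet_boost = doublet_boost,
    doublet_min_genes = as.integer(doublet_min_genes),
    lr_pairs_planted = lr_pairs_planted,
    lr_boost = lr_boost,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
}

config_error <- function(field, msg) {
  abort(sprintf("sim_config field '%s': %s", field, msg),
        class = "scnodule_config_error")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) config_error("n_genes", "must be positive")
  if (is.null(cfg$genes_per_chromosome)) {
    base <- cfg$n_genes %/% cfg$n_chromosomes
    extra <- cfg$n_genes %% cfg$n_chromosomes
    cfg$genes_per_chromosome <-
      base + as.integer(seq_len(cfg$n_chromosomes) <= extra)
  }
  gpc <- as.integer(cfg$genes_per_chromosome)
  if (length(gpc) != cfg$n_chromosomes) {
    config_error("genes_per_chromosome",
                 sprintf("length %d but n_chromosomes is %d",
                         length(gpc), cfg$n_chromosomes))
  }
  if (sum(gpc) != cfg$n_genes) {
    config_error("genes_per_chromosome",
                 sprintf("sums to %d but n_genes is %d", sum(gpc),
                         cfg$n_genes))
  }
  cfg$genes_per_chromosome <- gpc
  if (!all(.stages %in% names(cfg$n_samples))) {
    config_error("n_samples", "must name all of normal, pGGN, SN")
  }
  if (!all(names(cfg$cell_counts) %in% .stages)) {
    config_error("cell_counts", "stage names must be normal/pGGN/SN")
  }
  if (any(unlist(cfg$cell_counts) < 0)) {
    config_error("cell_counts", "counts must be non-negative")
  }
  mf <- cfg$malignant_fraction
  if (any(mf < 0 | mf > 1)) {
    config_error("malignant_fraction", "values must lie in [0, 1]")
  }
  if (cfg$mito_gene_count >= gpc[cfg$n_chromosomes]) {
    config_error("mito_gene_count",
                 "must be smaller than the last chromosome's gene count")
  }
  ac <- cfg$artifact_counts
  for (k in c("low_gene", "high_mito", "doublet")) {
    if (is.na(ac[k])) cfg$artifact_counts[k] <- 0
  }
  if (cfg$artifact_counts["doublet"] > 0 &&
      cfg$n_genes <= cfg$doublet_min_genes) {
    config_error("artifact_counts",
                 sprintf(paste0("doublets can only exceed %d detected genes ",
                                "when n_genes > %d (n_genes = %d)"),
                         cfg$doublet_min_genes, cfg$doublet_min_genes,
                         cfg$n_genes))
  }
  if (identical(cfg$cnv_segments, "auto")) {
    cfg$cnv_segments <- auto_clone_layout(cfg)
  } else if (identical(cfg$cnv_segments, "none")) {
    cfg$cnv_segments <- list()
  }
  validate_segments(cfg)
  if (!is.null(cfg$lr_pairs_planted)) {
    lr <- as_tibble(cfg$lr_pairs_planted)
    need <- c("ligand_gene", "receptor_gene", "sender_type", "receiver_type",
              "stage")
    if (!all(need %in% names(lr))) {
      config_error("lr_pairs_planted",
                   paste("needs columns", paste(need, collapse = ", ")))
    }
    cfg$lr_pairs_planted <- lr
  }
  cfg
}

sample_names <- function(cfg) {
  lapply(setNames(.stages, .stages),
         function(s) paste0(s, seq_len(cfg$n_samples[[s]])))
}

# One clone per tumor sample: a gain and a loss segment on distinct
# chromosome slots, offset so that no two samples share a segment.
auto_clone_layout <- function(cfg) {
  gpc <- cfg$genes_per_chromosome
  tumor <- unlist(sample_names(cfg)[.tumor_stages], use.names = FALSE)
  k <- cfg$n_chromosomes
  segs <- list()
  for (i in seq_along(tumor)) {
    gchr <- ((2L * (i - 1L)) %% k) + 1L
    lchr <- ((2L * i - 1L) %% k) + 1L
    off <- 1L + 50L * ((i - 1L) %/% k)
    len <- cfg$cnv_segment_genes
    lim <- function(chr) {
      n <- gpc[chr]
      if (chr == k) n <- n - cfg$mito_gene_count
      n
    }
    if (off + len - 1L > lim(gchr) || off + len - 1L > lim(lchr)) {
      config_error("cnv_segments",
                   "auto clone layout does not fit; pass explicit segments")
    }
    segs[[tumor[i]]] <- tibble(
      chromosome = paste0("chr", c(gchr, lchr)),
      start_gene_index = off,
      end_gene_index = off + len - 1L,
      copy_ratio = c(cfg$cnv_gain_ratio, cfg$cnv_loss_ratio))
  }
  segs
}

validate_segments <- function(cfg) {
  gpc <- cfg$genes_per_chromosome
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  for (sm in names(cfg$cnv_segments)) {
    seg <- as_tibble(cfg$cnv_segments[[sm]])
    if (any(seg$copy_ratio <= 0)) {
      config_error("cnv_segments", "every copy_ratio must be > 0")
    }
    ci <- match(seg$chromosome, chroms)
    if (anyNA(ci)) config_error("cnv_segments", "unknown chromosome")
    bad <- seg$start_gene_index < 1 | seg$end_gene_index > gpc[ci] |
      seg$start_gene_index > seg$end_gene_index
    if (any(bad)) {
      config_error("cnv_segments",
                   sprintf("segment out of range for sample %s", sm))
    }
    for (chr in unique(seg$chromosome)) {
      s <- seg[seg$chromosome == chr, ]
      s <- s[order(s$start_gene_index), ]
      if (nrow(s) > 1 &&
          any(s$start_gene_index[-1] <= s$end_gene_index[-nrow(s)])) {
        config_error("cnv_segments",
                     sprintf("overlapping segments within clone %s", sm))
      }
    }
  }
  invisible(cfg)
}

#' Apply a copy-number effect to an expression mean
#'
#' The simulator's model of a copy-number change: the expected expression of
#' a gene in a clone carrying a segment with copy ratio r is simply its
#' baseline mean multiplied by r.
#'
#' @param base_mean Non-negative baseline expression mean.
#' @param copy_ratio Positive fold-change (1 = neutral).
#' @return `base_mean * copy_ratio`.
#' @export
#' @examples
#' plant_cnv_effect(10, 1.5)
plant_cnv_effect <- function(base_mean, copy_ratio) {
  if (any(base_mean < 0)) {
    abort("base_mean must be non-negative", class = "scnodule_domain_error")
  }
  if (any(copy_ratio <= 0)) {
    abort("copy_ratio must be positive", class = "scnodule_domain_error")
  }
  base_mean * copy_ratio
}
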