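#' Parameters of the windowed CNV profiler
#'
#' @param gene_mean_cutoff Genes whose mean raw count across the reference
#'   cells falls below this are excluded (default 0.1).
#' @param window Odd number of genes in the positional moving average
#'   (default 101).
#' @param clamp Centered log-expression values are clipped to
#'   `[-clamp, clamp]` (default 3).
#' @param reference_cell_types Cell-type labels of the copy-neutral
#'   reference population; `NULL` (default) uses every type other than
#'   `observed_cell_types` — i.e. the stromal/immune compartment.
#' @param observed_cell_types Types whose CNV profiles are computed
#'   (default `"epithelial"`).
#' @return A `cnv_params` list.
#' @export
cnv_params <- function(gene_mean_cutoff = 0.1, window = 101, clamp = 3,
                       reference_cell_types = NULL,
                       observed_cell_types = "epithelial") {
  if (window < 1 || window %% 2 == 0) {
    abort("window must be an odd positive gene count",
          class = "scnodule_config_error")
  }
  if (clamp <= 0) abort("clamp must be positive",
                        class = "scnodule_config_error")
  if (gene_mean_cutoff < 0) abort("gene_mean_cutoff must be >= 0",
                                  class = "scnodule_config_error")
  structure(list(gene_mean_cutoff = gene_mean_cutoff,
                 window = as.integer(window), clamp = clamp,
                 reference_cell_types = reference_cell_types,
                 observed_cell_types = observed_cell_types),
            class = "cnv_params")
}

#' Order genes along the genome
#'
#' Stable sort by chromosome (in the order chromosomes first appear in the
#' table), then start position, with gene id as the final lexicographic
#' tie-break, so the ordering is deterministic under permutation of the
#' input.
#'
#' @param genes Gene table with `gene_id`, `chromosome`, `start`.
#' @return Integer permutation of `seq_len(nrow(genes))`.
#' @export
order_genes_genomically <- function(genes) {
  bad <- is.na(genes$chromosome) | is.na(genes$start)
  if (any(bad)) {
    abort(paste0("genes missing coordinates: ",
                 paste(head(genes$gene_id[bad], 5), collapse = ", ")),
          class = "scnodule_annotation_error")
  }
  chrom <- factor(genes$chromosome, levels = unique(genes$chromosome))
  order(chrom, genes$start, genes$gene_id)
}

#' Retain genes sufficiently expressed in the reference cells
#'
#' @param counts Raw gene x cell count matrix.
#' @param reference_cells Column index of the reference (copy-neutral)
#'   cells.
#' @param cutoff Minimum mean raw count over the reference cells
#'   (default 0.1).
#' @return Integer vector of retained gene rows.
#' @export
filter_genes_by_reference_mean <- function(counts, reference_cells,
                                           cutoff = 0.1) {
  if (!length(reference_cells)) {
    abort("reference cell set is empty", class = "scnodule_config_error")
  }
  mu <- Matrix::rowMeans(counts[, reference_cells, drop = FALSE])
  which(mu >= cutoff)
}

#' Center log-normalized expression on the reference population
#'
#' Subtracts, per gene, the mean log-normalized expression over the
#' reference cells, then clips every entry to `[-clamp, clamp]` so single
#' outlier transcripts cannot dominate the smoothed profile.
#'
#' @param norm Log-normalized gene x cell matrix (see [normalize_log()]).
#' @param reference_cells Column index of the reference cells.
#' @param clamp Clipping bound.
#' @return Dense centered matrix, same dimensions as `norm`.
#' @export
center_on_reference <- function(norm, reference_cells, clamp = 3) {
  if (!length(reference_cells)) {
    abort("reference cell set is empty", class = "scnodule_config_error")
  }
  ref_mean <- Matrix::rowMeans(norm[, reference_cells, drop = FALSE])
  out <- as.matrix(norm) - ref_mean
  out[out > clamp] <- clamp
  out[out < -clamp] <- -clamp
  out
}

#' Positional moving average along genomic gene order
#'
#' For each cell and gene position, averages the centered values over a
#' window of `window` genes centered at that position. The window is
#' truncated at chromosome boundaries (it shrinks near edges and never
#' crosses chromosomes). Afterwards each cell's median profile value is
#' subtracted so the modal copy state sits at 0.
#'
#' @param centered Centered gene x cell matrix, rows already in genomic
#'   order.
#' @param chromosomes Chromosome label per row of `centered`.
#' @param window Odd window size in genes.
#' @param recenter Subtract the per-cell median after smoothing
#'   (default `TRUE`).
#' @return Dense smoothed matrix, genes (positions) x cells.
#' @export
smooth_sliding_window <- function(centered, chromosomes, window = 101,
                                  recenter = TRUE) {
  if (window %% 2 == 0) {
    abort("window must be odd", class = "scnodule_config_error")
  }
  centered <- as.matrix(centered)
  chrom <- factor(chromosomes, levels = unique(chromosomes))
  sizes <- table(chrom)
  if (any(sizes < window)) {
    warn(sprintf("window (%d) exceeds the smallest chromosome (%d genes)",
                 window, min(sizes)))
  }
  h <- (window - 1L) %/% 2L
  out <- centered
  for (lev in levels(chrom)) {
    rows <- which(chrom == lev)
    g <- length(rows)
    cs <- rbind(0, apply(centered[rows, , drop = FALSE], 2, cumsum))
    lo <- pmax(1L, seq_len(g) - h)
    hi <- pmin(g, seq_len(g) + h)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  if (recenter && ncol(out)) {
    out <- sweep(out, 2, apply(out, 2, median))
  }
  out
}

#' Infer relative CNV profiles for one sample
#'
#' A simplified expression-based copy-number profiler: within one sample,
#' the stromal/immune cells are taken as a copy-neutral reference; genes
#' weakly expressed in that reference are dropped; the observed
#' (epithelial) cells' log-normalized expression is centered on the
#' reference mean, clipped, smoothed by a chromosome-truncated positional
#' moving average at gene resolution, and re-centered on the per-cell
#' median. Positive values are relative gains, negative values relative
#' losses, 0 is neutral.
#'
#' @param x A (QC-filtered) [cohort()].
#' @param sample Sample identifier to profile.
#' @param params A [cnv_params()].
#' @return A `cnv_matrix`: list with `values` (cells x positions, clipped to
#'   `[-clamp, clamp]`), `windows` (position table: chromosome, gene span,
#'   genomic span), `cells` (barcode/sample/stage of profiled cells) and
#'   `sample`.
#' @export
infer_cnv <- function(x, sample, params = cnv_params()) {
  rows <- which(x$cells$sample == sample)
  if (!length(rows)) {
    abort(sprintf("no cells for sample '%s'", sample),
          class = "scnodule_config_error")
  }
  sub <- subset_cohort(x, cells = rows)
  obs <- which(sub$cells$cell_type %in% params$observed_cell_types)
  ref <- if (is.null(params$reference_cell_types)) {
    which(!sub$cells$cell_type %in% params$observed_cell_types)
  } else {
    which(sub$cells$cell_type %in% params$reference_cell_types)
  }
  if (!length(ref)) {
    abort(sprintf("sample '%s' has no reference cells", sample),
          class = "scnodule_config_error")
  }
  ord <- order_genes_genomically(sub$genes)
  keep_local <- filter_genes_by_reference_mean(sub$counts[ord, , drop = FALSE],
                                               ref, params$gene_mean_cutoff)
  gidx <- ord[keep_local]
  norm <- normalize_log(sub)[gidx, , drop = FALSE]
  centered <- center_on_reference(norm, ref, params$clamp)
  sm <- smooth_sliding_window(centered[, obs, drop = FALSE],
                              sub$genes$chromosome[gidx],
                              params$window, recenter = TRUE)
  values <- Matrix::t(sm)
  values[values > params$clamp] <- params$clamp
  values[values < -params$clamp] <- -params$clamp
  g <- sub$genes[gidx, ]
  chrom <- factor(g$chromosome, levels = unique(g$chromosome))
  pos_in_chrom <- stats::ave(seq_along(gidx), chrom, FUN = seq_along)
  n_in_chrom <- stats::ave(seq_along(gidx), chrom, FUN = length)
  h <- (params$window - 1L) %/% 2L
  first <- pmax(1L, pos_in_chrom - h)
  last <- pmin(n_in_chrom, pos_in_chrom + h)
  chrom_off <- match(g$chromosome, g$chromosome) # first row of each chrom
  windows <- tibble(position = seq_along(gidx),
                    gene_id = g$gene_id,
                    chromosome = g$chromosome,
                    first_gene = g$gene_id[chrom_off + first - 1L],
                    last_gene = g$gene_id[chrom_off + last - 1L],
                    span_start = g$start[chrom_off + first - 1L],
                    span_end = g$start[chrom_off + last - 1L])
  structure(list(values = as.matrix(values),
                 windows = windows,
                 cells = sub$cells[obs, c("barcode", "sample", "stage",
                                          "cell_type")],
                 sample = sample,
                 params = params),
            class = "cnv_matrix")
}

#' Infer CNV profiles for several samples
#'
#' @param x A (QC-filtered) [cohort()].
#' @param samples Samples to profile; default: every sample with at least
#'   one observed-type cell in a tumor stage.
#' @param params A [cnv_params()].
#' @return Named list of `cnv_matrix` objects.
#' @export
infer_cnv_per_sample <- function(x, samples = NULL, params = cnv_params()) {
  if (is.null(samples)) {
    tumor <- x$cells$stage %in% .tumor_stages &
      x$cells$cell_type %in% params$observed_cell_types
    samples <- unique(x$cells$sample[tumor])
  }
  setNames(lapply(samples, function(sm) infer_cnv(x, sm, params)), samples)
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("<cnv_matrix> sample %s: %d cells x %d gene positions\n",
              x$sample, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @method tidy cnv_matrix
#' @export
tidy.cnv_matrix <- function(x, ...) {
  tibble(barcode = rep(x$cells$barcode, times = ncol(x$values)),
         position = rep(x$windows$position, each = nrow(x$values)),
         chromosome = rep(x$windows$chromosome, each = nrow(x$values)),
         value = as.vector(x$values))
}

#' @method glance cnv_matrix
#' @export
glance.cnv_matrix <- function(x, ...) {
  tibble(sample = x$sample,
         n_cells = nrow(x$values),
         n_positions = ncol(x$values),
         window = x$params$window,
         clamp = x$params$clamp,
         mean_abs_value = mean(abs(x$values)))
}
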