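#' QC thresholds for cell filtering
#'
#' The three rules applied to droplet scRNA-seq cells: too few detected
#' genes (empty or degraded droplets), too high a mitochondrial UMI fraction
#' (stressed or lysing cells), and too many detected genes (putative
#' doublets). All three comparisons are strict, so cells sitting exactly on
#' a threshold are kept.
#'
#' @param min_genes Cells with fewer detected genes are removed (default
#'   200).
#' @param max_mito_frac Cells with a higher mitochondrial UMI fraction are
#'   removed (default 0.10).
#' @param max_genes Cells with more detected genes are removed as doublets
#'   (default 5000).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200, max_mito_frac = 0.10,
                          max_genes = 5000) {
  if (!(min_genes > 0 && min_genes < max_genes)) {
    abort("need 0 < min_genes < max_genes", class = "scnodule_config_error")
  }
  if (!(max_mito_frac > 0 && max_mito_frac < 1)) {
    abort("max_mito_frac must lie in (0, 1)",
          class = "scnodule_config_error")
  }
  structure(list(min_genes = min_genes, max_mito_frac = max_mito_frac,
                 max_genes = max_genes), class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' @param x A [cohort()].
#' @return A tibble with one row per cell: `barcode`, `sample`, `stage`,
#'   `n_genes_detected` (genes with count > 0), `total_umi`, and
#'   `mito_frac` (mitochondrial UMI / total UMI, defined as 0 for empty
#'   cells).
#' @export
compute_qc_metrics <- function(x) {
  total <- Matrix::colSums(x$counts)
  ngene <- Matrix::colSums(x$counts > 0)
  mito_umi <- if (any(x$genes$is_mito)) {
    Matrix::colSums(x$counts[x$genes$is_mito, , drop = FALSE])
  } else {
    rep(0, ncol(x$counts))
  }
  tibble(barcode = x$cells$barcode,
         sample = x$cells$sample,
         stage = x$cells$stage,
         n_genes_detected = as.integer(ngene),
         total_umi = as.integer(total),
         mito_frac = unname(ifelse(total > 0, mito_umi / total, 0)))
}

#' Filter low-quality cells and putative doublets
#'
#' Removes a cell when it breaks at least one of the three strict rules of
#' [qc_thresholds()]; cells exactly on a boundary are kept. Every removed
#' cell is reported with the rule(s) that fired, so the filter is fully
#' auditable and idempotent (filtering the kept set again removes nothing).
#'
#' @param x A [cohort()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with
#'   * `kept` — the filtered [cohort()];
#'   * `removed` — tibble (`barcode`, `sample`, `stage`, metrics, `reason`)
#'     where `reason` is a comma-separated subset of
#'     `low_gene`, `high_mito`, `doublet`.
#' @export
apply_qc_filters <- function(x, thresholds = qc_thresholds()) {
  m <- compute_qc_metrics(x)
  low <- m$n_genes_detected < thresholds$min_genes
  mito <- m$mito_frac > thresholds$max_mito_frac
  dbl <- m$n_genes_detected > thresholds$max_genes
  drop <- low | mito | dbl
  reason <- vapply(seq_along(drop), function(i) {
    paste(c("low_gene", "high_mito", "doublet")[c(low[i], mito[i], dbl[i])],
          collapse = ",")
  }, character(1))
  removed <- m[drop, , drop = FALSE]
  removed$reason <- reason[drop]
  list(kept = subset_cohort(x, cells = which(!drop)),
       removed = as_tibble(removed))
}

#' Log-normalize UMI counts
#'
#' Counts-per-10k followed by natural log1p: for gene g in cell c,
#' `ln(1 + 1e4 * count[g,c] / total_umi[c])`. Cells with zero total UMI map
#' to all-zero columns. This is the de-facto droplet convention, so all
#' downstream log fold changes are natural-log.
#'
#' @param x A [cohort()], or a sparse/dense gene x cell count matrix.
#' @param scale_factor Per-cell depth target (default 1e4).
#' @return A sparse `dgCMatrix` of the same dimensions.
#' @export
normalize_log <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "cohort")) x$counts else
    methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix")
  total <- Matrix::colSums(counts)
  scl <- ifelse(total > 0, scale_factor / total, 0)
  out <- counts %*% Matrix::Diagonal(x = scl)
  out <- methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}
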