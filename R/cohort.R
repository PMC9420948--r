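#' Assemble a single-cell cohort object
#'
#' A `cohort` bundles a sparse gene x cell UMI count matrix with its two
#' annotation tables: one row per gene (genomic coordinates and a
#' mitochondrial flag) and one row per cell (sample of origin, radiological
#' stage, optional cell-type label). All downstream steps — QC,
#' normalization, CNV profiling, malignancy calling, differential expression
#' and ligand-receptor scoring — operate on this container.
#'
#' @param counts Sparse (or dense) non-negative integer matrix, genes in
#'   rows, cells in columns. Coerced to `Matrix::dgCMatrix`.
#' @param genes Data frame with columns `gene_id`, `chromosome`, `start`
#'   (0-based bp) and logical `is_mito`; optional `gene_name`. One row per
#'   matrix row, in matrix order.
#' @param cells Data frame with columns `barcode`, `sample`, `stage` (one of
#'   `"normal"`, `"pGGN"`, `"SN"`); optional `cell_type`. One row per matrix
#'   column, in matrix order.
#'
#' @return An object of class `cohort`: a list with elements `counts`,
#'   `genes` (tibble) and `cells` (tibble).
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
#'                           dims = c(3, 2))
#' genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                         chromosome = "chr1", start = c(0, 1e4, 2e4),
#'                         is_mito = FALSE)
#' cells <- tibble::tibble(barcode = c("c1", "c2"), sample = "s1",
#'                         stage = "normal")
#' cohort(m, genes, cells)
cohort <- function(counts, genes, cells) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  genes <- as_tibble(genes)
  cells <- as_tibble(cells)
  x <- structure(list(counts = counts, genes = genes, cells = cells),
                 class = "cohort")
  validate_cohort(x)
}

validate_cohort <- function(x) {
  counts <- x$counts
  genes <- x$genes
  cells <- x$cells
  if (nrow(counts) != nrow(genes)) {
    abort(sprintf(
      "count matrix has %d rows but gene table has %d rows",
      nrow(counts), nrow(genes)), class = "scnodule_format_error")
  }
  if (ncol(counts) != nrow(cells)) {
    abort(sprintf(
      "count matrix has %d columns but cell table has %d rows",
      ncol(counts), nrow(cells)), class = "scnodule_format_error")
  }
  for (col in c("gene_id", "chromosome", "start", "is_mito")) {
    if (!col %in% names(genes)) {
      abort(sprintf("gene table lacks required column '%s'", col),
            class = "scnodule_format_error")
    }
  }
  for (col in c("barcode", "sample", "stage")) {
    if (!col %in% names(cells)) {
      abort(sprintf("cell table lacks required column '%s'", col),
            class = "scnodule_format_error")
    }
  }
  if (length(counts@x) && any(counts@x < 0 | counts@x != round(counts@x))) {
    abort("counts must be non-negative integers",
          class = "scnodule_format_error")
  }
  key <- paste(cells$sample, cells$barcode, sep = "\r")
  if (anyDuplicated(key)) {
    abort("cell barcodes must be unique within a sample",
          class = "scnodule_format_error")
  }
  rownames(x$counts) <- genes$gene_id
  colnames(x$counts) <- cells$barcode
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  samples: %s\n",
              paste(unique(x$cells$sample), collapse = ", ")))
  st <- table(factor(x$cells$stage, levels = .stages))
  cat(sprintf("  stages:  %s\n",
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$counts)

#' Subset a cohort by gene and/or cell index
#'
#' @param x A [cohort()].
#' @param genes,cells Integer, logical or character (gene id / barcode)
#'   index into genes (rows) and cells (columns); `NULL` keeps all.
#' @return A `cohort` restricted to the requested rows/columns.
#' @export
subset_cohort <- function(x, genes = NULL, cells = NULL) {
  gi <- resolve_index(genes, x$genes$gene_id, nrow(x$counts))
  ci <- resolve_index(cells, x$cells$barcode, ncol(x$counts))
  cohort(x$counts[gi, ci, drop = FALSE],
         x$genes[gi, , drop = FALSE],
         x$cells[ci, , drop = FALSE])
}

resolve_index <- function(idx, ids, n) {
  if (is.null(idx)) return(seq_len(n))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      abort(paste0("unknown identifiers: ",
                   paste(head(idx[is.na(pos)], 5), collapse = ", ")),
            class = "scnodule_format_error")
    }
    return(pos)
  }
  idx
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally with a
#' `.gz` suffix) as written by [write_counts_10x()]. `features.tsv` carries
#' gene_id, gene_name, chromosome, start and is_mito columns;
#' `barcodes.tsv` carries the barcode and, when present, sample, stage and
#' cell_type columns (a bare one-column barcode file is also accepted).
#'
#' @param path Directory containing the triplet.
#' @return A [cohort()].
#' @export
read_counts_10x <- function(path) {
  mtx <- find_triplet_file(path, "matrix.mtx")
  feat <- find_triplet_file(path, "features.tsv")
  barc <- find_triplet_file(path, "barcodes.tsv")
  m <- Matrix::readMM(mtx)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  genes <- readr::read_tsv(feat, show_col_types = FALSE,
                           col_types = readr::cols(
                             chromosome = readr::col_character()))
  cells <- readr::read_tsv(barc, show_col_types = FALSE)
  if (ncol(cells) == 1L) names(cells) <- "barcode"
  if (!"sample" %in% names(cells)) cells$sample <- "sample1"
  if (!"stage" %in% names(cells)) cells$stage <- "normal"
  if (nrow(genes) != nrow(m)) {
    abort(sprintf("features.tsv has %d rows but matrix header declares %d",
                  nrow(genes), nrow(m)), class = "scnodule_format_error")
  }
  if (nrow(cells) != ncol(m)) {
    abort(sprintf("barcodes.tsv has %d rows but matrix header declares %d",
                  nrow(cells), ncol(m)), class = "scnodule_format_error")
  }
  if (length(m@x) && any(m@x != round(m@x))) {
    abort("matrix.mtx contains non-integer entries",
          class = "scnodule_format_error")
  }
  cohort(m, genes, cells)
}

find_triplet_file <- function(path, name) {
  for (cand in file.path(path, c(name, paste0(name, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  abort(sprintf("no %s[.gz] under %s", name, path),
        class = "scnodule_format_error")
}

#' Write a cohort as a 10x-style Matrix Market triplet
#'
#' Inverse of [read_counts_10x()]: writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` so that the triplet's logical content round-trips exactly.
#'
#' @param x A [cohort()].
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_counts_10x <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  feats <- x$genes
  if (!"gene_name" %in% names(feats)) feats$gene_name <- feats$gene_id
  readr::write_tsv(feats, file.path(path, "features.tsv"))
  readr::write_tsv(x$cells, file.path(path, "barcodes.tsv"))
  invisible(path)
}
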