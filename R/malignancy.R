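#' Parameters of the malignancy caller
#'
#' @param top_fraction Fraction of highest-CNV-score cells whose mean
#'   profile defines the malignant clone archetype (default 0.05). Note
#'   that this "reference" is the putative *malignant* archetype — the
#'   cells with the highest CNV burden — not a normal reference.
#' @param correlation_threshold Cells whose profile correlates with the
#'   archetype strictly above this are called malignant (default 0.3).
#' @param correlation_kind `"pearson"` (default) or `"spearman"` for
#'   sensitivity analysis.
#' @return A `malignancy_params` list.
#' @export
malignancy_params <- function(top_fraction = 0.05,
                              correlation_threshold = 0.3,
                              correlation_kind = c("pearson", "spearman")) {
  if (!(top_fraction > 0 && top_fraction < 1)) {
    abort("top_fraction must lie in (0, 1)",
          class = "scnodule_config_error")
  }
  if (abs(correlation_threshold) > 1) {
    abort("correlation_threshold must lie in [-1, 1]",
          class = "scnodule_config_error")
  }
  structure(list(top_fraction = top_fraction,
                 correlation_threshold = correlation_threshold,
                 correlation_kind = match.arg(correlation_kind)),
            class = "malignancy_params")
}

#' CNV burden score of a profile
#'
#' The mean of squared profile entries: 0 for a copy-neutral profile,
#' increasing with the magnitude of gains and losses.
#'
#' @param profile Numeric CNV profile (one cell's row), or a cells x
#'   positions matrix (scored row-wise).
#' @return Non-negative scalar, or one score per row for a matrix.
#' @export
#' @examples
#' cnv_score(c(0.1, -0.1, 0.2))
cnv_score <- function(profile) {
  if (is.matrix(profile)) {
    if (ncol(profile) == 0) {
      abort("empty profile", class = "scnodule_domain_error")
    }
    return(rowMeans(profile^2))
  }
  if (!length(profile)) {
    abort("empty profile", class = "scnodule_domain_error")
  }
  mean(profile^2)
}

#' Select the top-scoring cells as the clone archetype set
#'
#' Returns the `ceiling(top_fraction * n)` cells with the highest CNV
#' scores; boundary ties are broken by barcode lexicographic order so the
#' selection is deterministic under permutation of the input.
#'
#' @param scores Named (by barcode) numeric vector of CNV scores.
#' @param top_fraction Fraction of cells to select.
#' @return Character vector of selected barcodes.
#' @export
select_reference_cells <- function(scores, top_fraction = 0.05) {
  n <- length(scores)
  k <- ceiling(top_fraction * n)
  barcodes <- names(scores) %||% as.character(seq_len(n))
  ord <- order(-scores, barcodes)
  barcodes[ord[seq_len(k)]]
}

#' Mean CNV profile over a cell set
#'
#' @param cnv A `cnv_matrix` (see [infer_cnv()]).
#' @param reference Barcodes of the archetype cells.
#' @return Numeric vector, one value per gene position.
#' @export
reference_mean_profile <- function(cnv, reference) {
  idx <- match(reference, cnv$cells$barcode)
  if (!length(idx) || anyNA(idx)) {
    abort("reference cells empty or not in CNV matrix",
          class = "scnodule_domain_error")
  }
  colMeans(cnv$values[idx, , drop = FALSE])
}

#' Correlate each cell's CNV profile with the archetype profile
#'
#' Pearson (or Spearman) correlation between every cell's profile and the
#' archetype mean profile. When either vector has zero variance the
#' correlation is undefined and reported as `NA`; such cells are treated as
#' non-malignant downstream.
#'
#' @param cnv A `cnv_matrix`.
#' @param ref_profile Archetype profile from [reference_mean_profile()].
#' @param kind `"pearson"` or `"spearman"`.
#' @return Named numeric vector of correlations (NA where undefined).
#' @export
correlate_to_reference <- function(cnv, ref_profile,
                                   kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  if (length(ref_profile) != ncol(cnv$values)) {
    abort(sprintf("profile length %d does not match %d positions",
                  length(ref_profile), ncol(cnv$values)),
          class = "scnodule_domain_error")
  }
  r <- suppressWarnings(
    as.vector(cor(Matrix::t(cnv$values), ref_profile, method = kind)))
  setNames(r, cnv$cells$barcode)
}

#' Call malignant cells from archetype correlations
#'
#' A cell is malignant iff its correlation exceeds the threshold strictly;
#' undefined (NA) correlations are non-malignant. Archetype ("reference")
#' cells are classified by the same rule, keeping their `is_reference`
#' flag.
#'
#' @param correlations Named correlation vector from
#'   [correlate_to_reference()].
#' @param params A [malignancy_params()].
#' @param reference Barcodes of the archetype cells.
#' @return Tibble: `barcode`, `correlation`, `is_reference`,
#'   `is_malignant`.
#' @export
call_malignant <- function(correlations, params = malignancy_params(),
                           reference = character()) {
  tibble(barcode = names(correlations),
         correlation = unname(correlations),
         is_reference = names(correlations) %in% reference,
         is_malignant = unname(!is.na(correlations) &
                                 correlations > params$correlation_threshold))
}

#' Run the malignancy caller on each sample's CNV matrix
#'
#' The four-step per-sample procedure: (1) score each cell by the mean
#' square of its CNV profile; (2) take the top `top_fraction` of cells by
#' score as the malignant clone archetype; (3) average their profiles;
#' (4) call malignant every cell whose profile correlates with the
#' archetype above the threshold. Entirely deterministic.
#'
#' @param cnv_list Named list of `cnv_matrix` objects, one per tumor
#'   sample (see [infer_cnv_per_sample()]).
#' @param params A [malignancy_params()].
#' @return A `malignancy_call` object; use [tidy()] for the per-cell table
#'   (`barcode`, `sample`, `stage`, `cnv_score`, `correlation`,
#'   `is_reference`, `is_malignant`) and [glance()] for per-sample and
#'   per-stage malignant fractions.
#' @export
run_malignancy_per_sample <- function(cnv_list,
                                      params = malignancy_params()) {
  per_cell <- lapply(names(cnv_list), function(sm) {
    cnv <- cnv_list[[sm]]
    n <- nrow(cnv$values)
    if (n * params$top_fraction < 1) {
      warn(sprintf(
        "sample %s has %d cells; archetype set is a single cell", sm, n))
    }
    scores <- setNames(cnv_score(cnv$values), cnv$cells$barcode)
    ref <- select_reference_cells(scores, params$top_fraction)
    prof <- reference_mean_profile(cnv, ref)
    corr <- correlate_to_reference(cnv, prof, params$correlation_kind)
    calls <- call_malignant(corr, params, ref)
    calls$cnv_score <- unname(scores)
    calls$sample <- sm
    calls$stage <- cnv$cells$stage[match(calls$barcode, cnv$cells$barcode)]
    calls[, c("barcode", "sample", "stage", "cnv_score", "correlation",
              "is_reference", "is_malignant")]
  })
  cells <- bind_rows(per_cell)
  by_sample <- cells |>
    group_by(.data$sample, .data$stage) |>
    summarise(n_cells = n(),
              n_malignant = sum(.data$is_malignant),
              malignant_fraction = mean(.data$is_malignant),
              .groups = "drop")
  by_stage <- cells |>
    group_by(.data$stage) |>
    summarise(n_cells = n(),
              n_malignant = sum(.data$is_malignant),
              malignant_fraction = mean(.data$is_malignant),
              .groups = "drop")
  structure(list(cells = cells, by_sample = by_sample, by_stage = by_stage,
                 params = params),
            class = "malignancy_call")
}

#' @export
print.malignancy_call <- function(x, ...) {
  cat(sprintf("<malignancy_call> %d cells over %d samples\n",
              nrow(x$cells), nrow(x$by_sample)))
  print(x$by_sample)
  invisible(x)
}

#' @method tidy malignancy_call
#' @export
tidy.malignancy_call <- function(x, ...) x$cells

#' @method glance malignancy_call
#' @export
glance.malignancy_call <- function(x, per = c("sample", "stage"), ...) {
  switch(match.arg(per), sample = x$by_sample, stage = x$by_stage)
}
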