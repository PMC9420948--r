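#' Differential-expression thresholds
#'
#' The conventional droplet scRNA-seq DEG rule: two-sided Wilcoxon rank-sum
#' per gene with Benjamini-Hochberg adjustment over all tested genes, kept
#' when `|logFC| >= min_abs_logfc` and `p_adjusted <= alpha` (both
#' inclusive). `logFC` is the natural-log fold change of mean de-logged
#' normalized expression.
#'
#' @param min_abs_logfc Minimum absolute natural-log fold change
#'   (default 0.25).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A `deg_params` list.
#' @export
deg_params <- function(min_abs_logfc = 0.25, alpha = 0.05) {
  if (min_abs_logfc < 0) abort("min_abs_logfc must be >= 0",
                               class = "scnodule_config_error")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)",
                                       class = "scnodule_config_error")
  structure(list(min_abs_logfc = min_abs_logfc, alpha = alpha,
                 test = "wilcoxon", adjust = "benjamini_hochberg"),
            class = "deg_params")
}

#' Score and assign cell types from marker sets
#'
#' Each marker gene's log-normalized expression is z-scored across cells;
#' a cell's score for a type is the mean z-score over that type's marker
#' set, and the assignment is the argmax (ties broken by type-name
#' lexicographic order).
#'
#' @param norm Log-normalized gene x cell matrix with gene-id rownames.
#' @param marker_sets Named list `cell_type -> character vector of gene
#'   ids`, or a two-column data frame (`cell_type`, `gene_id`).
#' @return A list with `assignment` (tibble: `barcode`, `cell_type`,
#'   `score`) and `scores` (cells x types matrix).
#' @export
score_cell_types <- function(norm, marker_sets) {
  if (is.data.frame(marker_sets)) {
    marker_sets <- split(marker_sets$gene_id, marker_sets$cell_type)
  }
  missing <- setdiff(unlist(marker_sets), rownames(norm))
  if (length(missing)) {
    abort(paste0("marker genes absent from matrix: ",
                 paste(head(missing, 10), collapse = ", ")),
          class = "scnodule_config_error")
  }
  types <- sort(names(marker_sets))
  genes <- unique(unlist(marker_sets))
  m <- as.matrix(norm[genes, , drop = FALSE])
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  scores <- vapply(types, function(t) {
    colMeans(z[marker_sets[[t]], , drop = FALSE])
  }, numeric(ncol(m)))
  scores <- matrix(scores, ncol = length(types),
                   dimnames = list(colnames(norm), types))
  best <- apply(scores, 1, function(s) types[which.max(s)])
  tibble_out <- tibble(barcode = colnames(norm) %||%
                         as.character(seq_len(ncol(norm))),
                       cell_type = unname(best),
                       score = scores[cbind(seq_len(nrow(scores)),
                                            match(best, types))])
  list(assignment = tibble_out, scores = scores)
}

#' Cell-type composition by stage
#'
#' @param cells Cell table with `stage` and `cell_type` columns (e.g. the
#'   `cells` element of a [cohort()]).
#' @return A `composition` tibble: `stage`, `cell_type`, `n`,
#'   `proportion` (summing to 1 within each stage).
#' @export
composition_by_stage <- function(cells) {
  present <- intersect(.stages, unique(cells$stage))
  empty <- setdiff(.stages, present)
  if (length(empty)) {
    warn(paste("no cells in stage(s):", paste(empty, collapse = ", ")))
  }
  out <- cells |>
    count(.data$stage, .data$cell_type, name = "n") |>
    group_by(.data$stage) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(stage = factor(.data$stage, levels = .stages)) |>
    arrange(.data$stage, .data$cell_type)
  class(out) <- c("composition", class(out))
  out
}

# Vectorised two-sided Wilcoxon rank-sum over the rows of a matrix.
# Normal approximation with tie correction and continuity correction for
# groups larger than `exact_max`; exact distribution (no ties) otherwise.
rank_sum_rows <- function(m, in_a, exact_max = 20) {
  na <- sum(in_a)
  nb <- sum(!in_a)
  n <- na + nb
  exact_ok <- na <= exact_max && nb <= exact_max
  p <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    r <- rank(x)
    w <- sum(r[in_a]) - na * (na + 1) / 2    # Mann-Whitney U for group A
    ties <- tabulate(match(x, unique(x)))
    if (length(ties) == 1L) {                # all values equal: no evidence
      p[i] <- 1
      next
    }
    if (exact_ok && !any(ties > 1)) {
      p[i] <- min(1, 2 * min(pwilcox(w, na, nb),
                             pwilcox(nb * na - w, nb, na)))
    } else {
      mu <- na * nb / 2
      tie_term <- sum(ties^3 - ties)
      sig <- sqrt(na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1))))
      z <- w - mu
      z <- sign(z) * max(0, abs(z) - 0.5) / sig  # continuity correction
      p[i] <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  p
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test on log-normalized values,
#' BH adjustment over all tested genes, and the natural-log fold change
#' `ln(mean(expm1(norm_A)) + 1) - ln(mean(expm1(norm_B)) + 1)`. Genes are
#' reported as `up` when group A exceeds group B.
#'
#' @param norm Log-normalized gene x cell matrix with gene-id rownames.
#' @param group_a,group_b Barcodes (or column indices) of the two cell
#'   groups; both need at least 3 cells.
#' @param params A [deg_params()].
#' @param filter Keep only rows passing the thresholds (default `TRUE`);
#'   `FALSE` returns every tested gene (with a `passes` column), which is
#'   what calibration studies and volcano plots need.
#' @param contrast,cell_type Labels recorded in the output.
#' @return A `deg_table` tibble: `gene_id`, `logFC`, `p_value`,
#'   `p_adjusted`, `direction`, `contrast`, `cell_type` (and `passes` when
#'   `filter = FALSE`).
#' @export
wilcoxon_deg <- function(norm, group_a, group_b, params = deg_params(),
                         filter = TRUE, contrast = "A_vs_B",
                         cell_type = NA_character_) {
  ia <- resolve_index(group_a, colnames(norm), ncol(norm))
  ib <- resolve_index(group_b, colnames(norm), ncol(norm))
  if (length(ia) < 3 || length(ib) < 3) {
    abort("both groups need at least 3 cells",
          class = "scnodule_domain_error")
  }
  m <- as.matrix(norm[, c(ia, ib), drop = FALSE])
  in_a <- seq_along(c(ia, ib)) <= length(ia)
  mean_a <- rowMeans(expm1(m[, in_a, drop = FALSE]))
  mean_b <- rowMeans(expm1(m[, !in_a, drop = FALSE]))
  logfc <- unname(log(mean_a + 1) - log(mean_b + 1))
  p <- rank_sum_rows(m, in_a)
  padj <- p.adjust(p, method = "BH")
  out <- tibble(gene_id = rownames(norm) %||%
                  as.character(seq_len(nrow(norm))),
                logFC = logfc,
                p_value = p,
                p_adjusted = padj,
                direction = ifelse(logfc >= 0, "up", "down"),
                contrast = contrast,
                cell_type = cell_type)
  pass <- abs(out$logFC) >= params$min_abs_logfc &
    out$p_adjusted <= params$alpha
  if (filter) {
    out <- out[pass, , drop = FALSE]
  } else {
    out$passes <- pass
  }
  attr(out, "n_genes_tested") <- nrow(m)
  class(out) <- c("deg_table", class(out))
  out
}

#' Stage-dependent differentially expressed genes
#'
#' A gene is stage-dependent for a cell type when it moves in the *same*
#' direction in both adjacent contrasts of the progression axis — up in
#' pGGN vs normal *and* up in SN vs pGGN (stage-dependent up), or down in
#' both (stage-dependent down). Genes with any other pattern are excluded.
#' For the looser "differential vs normal in both tumor stages" reading,
#' pass the pGGN-vs-normal and SN-vs-normal tables instead; the
#' same-direction intersection logic is identical.
#'
#' @param deg_first,deg_second Two filtered `deg_table`s (see
#'   [wilcoxon_deg()]) computed per cell type on the same gene universe.
#' @return Tibble: `gene_id`, `cell_type`, `direction`.
#' @export
stage_dependent_degs <- function(deg_first, deg_second) {
  inner_join(
    as_tibble(deg_first)[, c("gene_id", "cell_type", "direction")],
    as_tibble(deg_second)[, c("gene_id", "cell_type", "direction")],
    by = c("gene_id", "cell_type", "direction")) |>
    distinct() |>
    arrange(.data$cell_type, .data$direction, .data$gene_id)
}
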