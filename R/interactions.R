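#' Parameters of the ligand-receptor permutation test
#'
#' @param n_permutations Number of global cell-type label shuffles
#'   (default 1000). One shuffle per iteration is shared by every pair and
#'   type pair, preserving cross-pair dependence.
#' @param alpha Significance threshold on the permutation p-value
#'   (default 0.05, inclusive).
#' @param min_expr_fraction Minimum fraction of expressing cells required
#'   of the ligand in the sender type and the receptor in the receiver
#'   type (default 0.10).
#' @param seed Integer seed for the shuffles.
#' @return An `lr_params` list.
#' @export
lr_params <- function(n_permutations = 1000, alpha = 0.05,
                      min_expr_fraction = 0.10, seed = 1L) {
  if (n_permutations < 1) abort("n_permutations must be >= 1",
                                class = "scnodule_config_error")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)",
                                       class = "scnodule_config_error")
  if (min_expr_fraction < 0 || min_expr_fraction >= 1) {
    abort("min_expr_fraction must lie in [0, 1)",
          class = "scnodule_config_error")
  }
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 min_expr_fraction = min_expr_fraction,
                 seed = as.integer(seed)), class = "lr_params")
}

#' Interaction mean of a ligand-receptor pair
#'
#' The average of the ligand's mean expression over the sender cells and
#' the receptor's mean expression over the receiver cells. When either
#' cluster mean is exactly 0 the value is still reported but flagged
#' inactive (an unexpressed partner nullifies the interaction).
#'
#' @param norm Log-normalized gene x cell matrix with gene-id rownames.
#' @param ligand,receptor Gene ids.
#' @param sender_cells,receiver_cells Barcodes or column indices.
#' @return List with `value` (the mean) and `inactive` (logical).
#' @export
interaction_mean <- function(norm, ligand, receptor, sender_cells,
                             receiver_cells) {
  for (g in c(ligand, receptor)) {
    if (!g %in% rownames(norm)) {
      abort(sprintf("unknown gene '%s'", g),
            class = "scnodule_config_error")
    }
  }
  is_ <- resolve_index(sender_cells, colnames(norm), ncol(norm))
  ir <- resolve_index(receiver_cells, colnames(norm), ncol(norm))
  ml <- mean(norm[ligand, is_])
  mr <- mean(norm[receptor, ir])
  list(value = (ml + mr) / 2, inactive = ml == 0 || mr == 0)
}

#' Cluster expression-fraction filter
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param gene Gene id.
#' @param cells Barcodes or column indices of the cluster.
#' @param min_expr_fraction Required fraction of cells with expression > 0.
#' @return `TRUE` when the fraction of expressing cells reaches the
#'   threshold.
#' @export
expression_fraction_filter <- function(norm, gene, cells,
                                       min_expr_fraction = 0.10) {
  idx <- resolve_index(cells, colnames(norm), ncol(norm))
  mean(norm[gene, idx] > 0) >= min_expr_fraction
}

# Shared permutation engine: one global label shuffle per iteration,
# cluster means recomputed by matrix product, exceedance counts
# accumulated for every (pair, sender, receiver) combo at once.
permute_interactions <- function(m, labels, combos, n_permutations) {
  types <- sort(unique(labels))
  n <- length(labels)
  ind <- outer(labels, types, "==")
  ind <- sweep(ind * 1, 2, pmax(1, colSums(ind)), "/")
  g_obs <- m %*% ind
  colnames(g_obs) <- types
  li <- match(combos$ligand, rownames(m))
  ri <- match(combos$receptor, rownames(m))
  si <- match(combos$sender, types)
  ti <- match(combos$receiver, types)
  obs <- (g_obs[cbind(li, si)] + g_obs[cbind(ri, ti)]) / 2
  exceed <- integer(nrow(combos))
  for (b in seq_len(n_permutations)) {
    gp <- m %*% ind[sample.int(n), , drop = FALSE]
    val <- (gp[cbind(li, si)] + gp[cbind(ri, ti)]) / 2
    exceed <- exceed + (val >= obs)
  }
  list(observed = obs,
       p_value = (1 + exceed) / (1 + n_permutations),
       cluster_means = g_obs)
}

#' Permutation p-value for one ligand-receptor pair
#'
#' Shuffles the cell-type labels `n_permutations` times and reports
#' `p = (1 + #\{permuted mean >= observed mean\}) / (1 + n_permutations)`,
#' so p-values live on the grid `k/(n_permutations + 1)` and are never
#' exactly 0.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param ligand,receptor Gene ids.
#' @param labels Cell-type label per column of `norm`.
#' @param sender,receiver Cell-type labels of the sender and receiver
#'   clusters.
#' @param params An [lr_params()].
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(norm, ligand, receptor, labels, sender,
                               receiver, params = lr_params()) {
  for (ty in c(sender, receiver)) {
    if (!ty %in% labels) {
      abort(sprintf("cell type '%s' absent from labels", ty),
            class = "scnodule_domain_error")
    }
  }
  m <- as.matrix(norm[unique(c(ligand, receptor)), , drop = FALSE])
  combos <- tibble(ligand = ligand, receptor = receptor, sender = sender,
                   receiver = receiver)
  set.seed(params$seed)
  permute_interactions(m, labels, combos, params$n_permutations)$p_value
}

#' Score ligand-receptor interactions between cell types, per stage
#'
#' For every stage, every pair in the table and every ordered (sender,
#' receiver) cell-type pair: the interaction mean, the cluster
#' expression fractions, and a label-permutation p-value. An interaction
#' is significant when `p <= alpha` *and* both expression-fraction
#' filters pass; pairs with an unexpressed partner are additionally
#' flagged inactive.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param cells Cell table aligned to `norm` columns, with `barcode`,
#'   `cell_type` and `stage`.
#' @param pairs Pair table: `pair_id`, `ligand`, `receptor` (gene ids).
#' @param params An [lr_params()].
#' @param stages Stages to analyze (default: those present among
#'   `cells$stage` that have at least 2 cell types).
#' @return An `interaction_table` tibble: `stage`, `pair_id`, `ligand`,
#'   `receptor`, `sender`, `receiver`, `interaction_mean`,
#'   `ligand_fraction`, `receptor_fraction`, `inactive`, `p_value`,
#'   `significant`.
#' @export
score_interactions <- function(norm, cells, pairs, params = lr_params(),
                               stages = NULL) {
  pairs <- as_tibble(pairs)
  if (anyDuplicated(pairs$pair_id)) {
    abort("pair ids must be unique", class = "scnodule_config_error")
  }
  missing <- setdiff(unique(c(pairs$ligand, pairs$receptor)),
                     rownames(norm))
  if (length(missing)) {
    abort(paste0("pair genes absent from matrix: ",
                 paste(head(missing, 10), collapse = ", ")),
          class = "scnodule_config_error")
  }
  if (is.null(stages)) {
    stages <- intersect(.stages, unique(cells$stage))
  }
  genes_used <- unique(c(pairs$ligand, pairs$receptor))
  set.seed(params$seed)
  out <- lapply(stages, function(st) {
    idx <- which(cells$stage == st)
    labels <- cells$cell_type[idx]
    types <- sort(unique(labels))
    if (length(types) < 2) return(NULL)
    m <- as.matrix(norm[genes_used, idx, drop = FALSE])
    combos <- tidyr::expand_grid(pairs, sender = types, receiver = types)
    res <- permute_interactions(m, labels, combos, params$n_permutations)
    frac <- (m > 0) %*%
      sweep(outer(labels, types, "==") * 1, 2,
            pmax(1, colSums(outer(labels, types, "=="))), "/")
    li <- match(combos$ligand, genes_used)
    ri <- match(combos$receptor, genes_used)
    si <- match(combos$sender, types)
    ti <- match(combos$receiver, types)
    tibble(stage = st,
           pair_id = combos$pair_id,
           ligand = combos$ligand, receptor = combos$receptor,
           sender = combos$sender, receiver = combos$receiver,
           interaction_mean = res$observed,
           ligand_fraction = frac[cbind(li, si)],
           receptor_fraction = frac[cbind(ri, ti)],
           inactive = res$cluster_means[cbind(li, si)] == 0 |
             res$cluster_means[cbind(ri, ti)] == 0,
           p_value = res$p_value,
           significant = res$p_value <= params$alpha &
             frac[cbind(li, si)] >= params$min_expr_fraction &
             frac[cbind(ri, ti)] >= params$min_expr_fraction)
  })
  out <- bind_rows(out)
  class(out) <- c("interaction_table", class(out))
  out
}

#' Stage-wise interaction networks and their difference
#'
#' @param interactions An `interaction_table` (see [score_interactions()])
#'   covering one or more stages on a shared pair table.
#' @return A list with
#'   * `edges` — significant (stage, pair, sender, receiver) rows;
#'   * `difference` — triples significant in exactly one stage, with the
#'     stage they are specific to.
#' @export
build_interaction_network <- function(interactions) {
  edges <- as_tibble(interactions) |>
    filter(.data$significant) |>
    select("stage", "pair_id", "ligand", "receptor", "sender", "receiver",
           "interaction_mean", "p_value")
  difference <- edges |>
    group_by(.data$pair_id, .data$ligand, .data$receptor, .data$sender,
             .data$receiver) |>
    summarise(n_stages = n(), specific_to = ifelse(n() == 1,
                                                   .data$stage[1],
                                                   NA_character_),
              .groups = "drop") |>
    filter(.data$n_stages == 1) |>
    select(-"n_stages")
  list(edges = edges, difference = difference)
}
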