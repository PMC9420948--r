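#' Run the full nodule-progression pipeline on a cohort
#'
#' Chains every stage of the analysis: QC filtering, log-normalization,
#' stage composition, per-sample CNV inference and malignancy calling on
#' epithelial cells of tumor samples, the two adjacent-stage
#' differential-expression contrasts with stage-dependent DEG
#' classification, and per-stage ligand-receptor interaction scoring.
#' Deterministic for a fixed input cohort and `lr_params` seed.
#'
#' @param x A [cohort()] with `cell_type` annotations (e.g. from
#'   [generate_cohort()], or annotated via [score_cell_types()]).
#' @param lr_pairs Optional pair table (`pair_id`, `ligand`, `receptor`)
#'   for interaction scoring; `NULL` skips that stage.
#' @param qc A [qc_thresholds()].
#' @param cnv A [cnv_params()].
#' @param malignancy A [malignancy_params()].
#' @param deg A [deg_params()].
#' @param lr An [lr_params()].
#' @param deg_cell_type Cell type on which the progression DEG contrasts
#'   are computed (default `"epithelial"`).
#' @return A list: `qc` (kept cohort + removed table), `composition`,
#'   `cnv` (list of `cnv_matrix`), `malignancy`, `deg` (both contrasts,
#'   unfiltered and filtered), `stage_dependent`, `interactions`,
#'   `network`.
#' @export
run_pipeline <- function(x, lr_pairs = NULL,
                         qc = qc_thresholds(), cnv = cnv_params(),
                         malignancy = malignancy_params(),
                         deg = deg_params(), lr = lr_params(),
                         deg_cell_type = "epithelial") {
  qcres <- apply_qc_filters(x, qc)
  kept <- qcres$kept
  norm <- normalize_log(kept)
  comp <- composition_by_stage(kept$cells)

  cnv_list <- infer_cnv_per_sample(kept, params = cnv)
  mal <- run_malignancy_per_sample(cnv_list, malignancy)

  grp <- function(stage) {
    which(kept$cells$stage == stage & kept$cells$cell_type == deg_cell_type)
  }
  degs <- list()
  if (length(grp("normal")) >= 3 && length(grp("pGGN")) >= 3) {
    degs$pGGN_vs_normal <- wilcoxon_deg(
      norm, grp("pGGN"), grp("normal"), deg,
      contrast = "pGGN_vs_normal", cell_type = deg_cell_type)
  }
  if (length(grp("pGGN")) >= 3 && length(grp("SN")) >= 3) {
    degs$SN_vs_pGGN <- wilcoxon_deg(
      norm, grp("SN"), grp("pGGN"), deg,
      contrast = "SN_vs_pGGN", cell_type = deg_cell_type)
  }
  stage_dep <- if (length(degs) == 2) {
    stage_dependent_degs(degs$pGGN_vs_normal, degs$SN_vs_pGGN)
  } else {
    NULL
  }

  interactions <- network <- NULL
  if (!is.null(lr_pairs)) {
    interactions <- score_interactions(norm, kept$cells, lr_pairs, lr)
    network <- build_interaction_network(interactions)
  }

  list(qc = qcres, composition = comp, cnv = cnv_list, malignancy = mal,
       deg = degs, stage_dependent = stage_dep,
       interactions = interactions, network = network)
}
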