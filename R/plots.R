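#' Stacked-bar composition plot by stage
#'
#' @param x A `composition` tibble from [composition_by_stage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition
#' @export
autoplot.composition <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$stage, y = .data$proportion,
                                  fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of cells", fill = "cell type") +
    ggplot2::theme_minimal()
}

#' CNV heatmap: cells by genomic position
#'
#' @param x A `cnv_matrix` from [infer_cnv()].
#' @param ... Unused.
#' @return A ggplot object; cells ordered by CNV score, red gains and blue
#'   losses along genomic gene order, faceted by chromosome.
#' @method autoplot cnv_matrix
#' @export
autoplot.cnv_matrix <- function(x, ...) {
  long <- tidy(x)
  ord <- x$cells$barcode[order(cnv_score(x$values))]
  long$barcode <- factor(long$barcode, levels = ord)
  long$chromosome <- factor(long$chromosome,
                            levels = unique(x$windows$chromosome))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$barcode,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "genomic gene position", y = NULL,
                  fill = "relative CNV",
                  title = sprintf("sample %s", x$sample)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' CNV score vs archetype correlation, per sample
#'
#' @param x A `malignancy_call` from [run_malignancy_per_sample()].
#' @param ... Unused.
#' @return A ggplot object; the dashed line is the correlation threshold.
#' @method autoplot malignancy_call
#' @export
autoplot.malignancy_call <- function(x, ...) {
  ggplot2::ggplot(x$cells,
                  ggplot2::aes(x = .data$correlation, y = .data$cnv_score,
                               colour = .data$is_malignant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = x$params$correlation_threshold,
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(x = "correlation with clone archetype",
                  y = "CNV score (mean square)", colour = "malignant") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param x A `deg_table` from [wilcoxon_deg()], ideally computed with
#'   `filter = FALSE` so non-significant genes are shown too.
#' @param params The [deg_params()] used (drawn as threshold lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(x, params = deg_params(), ...) {
  x <- as_tibble(x)
  x$passes <- x$passes %||%
    (abs(x$logFC) >= params$min_abs_logfc & x$p_adjusted <= params$alpha)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$logFC,
                                  y = -log10(pmax(.data$p_adjusted, 1e-300)),
                                  colour = .data$passes)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * params$min_abs_logfc,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(params$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log fold change (natural log)",
                  y = "-log10 adjusted p", colour = "passes") +
    ggplot2::theme_minimal()
}

#' Dot plot of ligand-receptor interactions
#'
#' @param x An `interaction_table` from [score_interactions()]; only
#'   significant rows are drawn.
#' @param ... Unused.
#' @return A ggplot object: pair vs sender-receiver, dot size encoding
#'   -log10 p, colour the interaction mean, faceted by stage.
#' @method autoplot interaction_table
#' @export
autoplot.interaction_table <- function(x, ...) {
  sig <- as_tibble(x) |> filter(.data$significant)
  sig$type_pair <- paste(sig$sender, sig$receiver, sep = " > ")
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$type_pair, y = .data$pair_id,
                                    size = -log10(.data$p_value),
                                    colour = .data$interaction_mean)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stage)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "sender > receiver", y = "ligand-receptor pair",
                  size = "-log10 p", colour = "mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
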