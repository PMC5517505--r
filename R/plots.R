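#' Volcano plot of a DEG table
#'
#' Plots `log2_ratio` against `-log10(fdr)` for all tested genes of a
#' comparison, highlighting the genes passing both gates.
#'
#' @param deg_table output of [call_degs()] with `keep_all = TRUE`.
#' @param fdr_threshold,fc_threshold gates drawn as guide lines (should
#'   match the call).
#' @return a ggplot object.
#' @export
plot_volcano <- function(deg_table, fdr_threshold = 0.001, fc_threshold = 2) {
  stopifnot("significant" %in% names(deg_table))
  dat <- dplyr::mutate(deg_table,
                       neglog_fdr = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2_ratio, .data$neglog_fdr,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 ratio (treatment / reference)",
                  y = "-log10 FDR", colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Horizontal bar plot of top enriched terms
#'
#' @param enrichment output of [enrich_gene_sets()].
#' @param top_n terms per namespace to show (by raw p).
#' @return a ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 10) {
  dat <- enrichment |>
    dplyr::group_by(.data$namespace) |>
    dplyr::slice_min(.data$p_raw, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(term = stats::reorder(.data$term_id, -.data$p_raw))
  ggplot2::ggplot(dat, ggplot2::aes(-log10(pmax(.data$p_fdr, 1e-300)),
                                    .data$term, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$namespace), scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "-log10 FDR-adjusted p", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a co-expression network's degree/core structure
#'
#' Scatter of node degree against core number; the hubs a degree/k-core
#' screen would nominate sit in the upper right.
#'
#' @param object a `coexpression_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  ggplot2::ggplot(object$nodes,
                  ggplot2::aes(.data$degree, .data$core_number)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "degree", y = "core number") +
    ggplot2::theme_minimal()
}
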