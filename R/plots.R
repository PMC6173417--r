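# ggplot2 autoplot methods for quick inspection of each result type.

#' @exportS3Method ggplot2::autoplot
autoplot.vasc_de <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$adj_p <= alpha & !df$all_zero
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("adj p <= %g", alpha)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vasc_scores <- function(object, ...) {
  df <- tidy(object)
  if (!"call" %in% names(df)) df$call <- "none"
  df <- df[is.finite(df$score), , drop = FALSE]
  df$pathway <- factor(df$pathway, levels = df$pathway[order(df$score)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$pathway,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "firebrick", down = "steelblue",
                                          none = "grey70")) +
    ggplot2::labs(x = "pathway score (mean LFC / sd LFC)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vasc_gsea <- function(object, q_max = 0.05, ...) {
  df <- tidy(object)
  df$significant <- !is.na(df$fdr_q) & df$fdr_q <= q_max
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes,
                                   y = stats::reorder(.data$set_name, .data$nes),
                                   colour = .data$significant,
                                   size = .data$n_genes_used)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = sprintf("FDR q <= %g", q_max)) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vasc_ddct <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fold_change)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::labs(y = "fold change (2^-ddCT)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pathways-by-timepoints matrix
#'
#' Tile plot of the matrix produced by [build_heatmap_matrix()].
#'
#' @param heatmap Tibble with a `pathway` column plus one column per
#'   timepoint.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(heatmap) {
  long <- tidyr::pivot_longer(heatmap, -"pathway", names_to = "timepoint",
                              values_to = "value")
  long$timepoint <- factor(long$timepoint, levels = setdiff(names(heatmap), "pathway"))
  long$pathway <- factor(long$pathway, levels = rev(heatmap$pathway))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$pathway,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
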