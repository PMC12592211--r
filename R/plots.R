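# ggplot2 visualisations for the main result types.

#' Plot YGS window scores along the genome
#'
#' Percent unmatched single-copy k-mers per window, one panel per
#' chromosome, with the candidate-retention threshold drawn.
#'
#' @param object A `uv_ygs_scores` tibble from [ygs_score_windows()].
#' @param threshold_pct Threshold line to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uv_ygs_scores
#' @export
autoplot.uv_ygs_scores <- function(object, threshold_pct = 50, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$pct_unmatched)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "% unmatched single-copy k-mers") +
    ggplot2::theme_minimal()
}

#' Plot normalized male and female coverage with window classes
#'
#' @param classes Output of [classify_windows()].
#' @return A ggplot object.
#' @export
plot_coverage_classes <- function(classes) {
  long <- classes |>
    tidyr::pivot_longer(c("norm_male", "norm_female"),
                        names_to = "sex", values_to = "norm_depth") |>
    mutate(sex = sub("norm_", "", .data$sex))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$norm_depth,
                               colour = .data$sex)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.75, 1.25),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "normalized depth",
                  colour = "read set") +
    ggplot2::theme_minimal()
}

#' Plot the gametologue Ks distribution
#'
#' @param kaks Tibble of [ng86_kaks()] results (one row per pair).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(kaks, bins = 30) {
  ggplot2::ggplot(kaks, ggplot2::aes(x = .data$Ks)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white", na.rm = TRUE) +
    ggplot2::labs(x = expression(K[s]), y = "gametologue pairs") +
    ggplot2::theme_minimal()
}

#' Plot per-node expected SDR gene counts on the species tree
#'
#' @param events Output of [call_events()].
#' @param tree The species tree.
#' @return A ggplot object (node index vs expected gene count).
#' @export
plot_expected_genes <- function(events, tree) {
  labs <- node_labels(tree)
  df <- events$expected_genes |>
    mutate(node = factor(.data$node, levels = labs),
           is_tip = .data$node %in% tree$tip.label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node,
                                   y = .data$expected_genes,
                                   fill = .data$is_tip)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "expected SDR gene count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}
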