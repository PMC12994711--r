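# ggplot2 displays for the main result types

#' Plot per-gene cross-population concurrence counts
#'
#' Horizontal bars, one pair per gene, showing in how many populations the
#' gene falls in the extreme low tail of each statistic; bars reaching the
#' dashed threshold line in every statistic mark concurrent hits.
#'
#' @param concurrence Output of [concurrence()] (or the `concurrence`
#'   element of [run_scan()]).
#' @param threshold Minimum-population threshold drawn as a dashed line.
#' @param top Show only the `top` genes with the highest total counts
#'   (default 30; `Inf` for all).
#' @return A ggplot object.
#' @export
plot_concurrence <- function(concurrence, threshold = 10, top = 30) {
  count_cols <- grep("^count_", names(concurrence), value = TRUE)
  long <- concurrence |>
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(count_cols)))) |>
    dplyr::slice_max(.data$total, n = top, with_ties = FALSE) |>
    tidyr::pivot_longer(dplyr::all_of(count_cols),
      names_to = "statistic", values_to = "n_populations"
    ) |>
    dplyr::mutate(
      statistic = sub("^count_", "", .data$statistic),
      gene_id = stats::reorder(.data$gene_id, .data$total)
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n_populations, y = .data$gene_id, fill = .data$statistic,
    alpha = .data$n_populations >= threshold
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
      width = 0.7) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
      colour = "red") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
      guide = "none") +
    ggplot2::labs(
      x = "populations with extreme low values", y = NULL,
      fill = "statistic"
    ) +
    ggplot2::theme_minimal()
}

#' Plot window statistics along the genome
#'
#' @param stats Window-statistics table (see [compute_window_stats()]),
#'   optionally with a `population` column (facetted).
#' @param statistic Column to draw (default `"tajimas_d"`).
#' @return A ggplot object.
#' @export
plot_window_stats <- function(stats, statistic = "tajimas_d") {
  assert_columns(stats, c("start", statistic), "window-statistics table")
  p <- ggplot2::ggplot(stats, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data[[statistic]]
  )) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "position (bp)", y = statistic) +
    ggplot2::theme_minimal()
  if ("population" %in% names(stats)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$population))
  }
  p
}

#' Autoplot the resampled background comparison
#'
#' Histogram of the per-iteration Wilcoxon p-values of
#' [pi_background_comparison()], with the median marked.
#'
#' @param object A `selscape_resample` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selscape_resample <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$iterations, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = g$median_p, linetype = "dashed") +
    ggplot2::labs(
      x = "Wilcoxon rank-sum p-value (per iteration)", y = "iterations",
      title = sprintf(
        "candidate vs background nucleotide diversity (median p = %.3g)",
        g$median_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
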