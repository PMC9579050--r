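# ggplot2 autoplot() methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a correlation suite
#'
#' One bar per receptor family showing Pearson r against the reference
#' family, with asterisks marking Bonferroni-significant correlations.
#'
#' @param object a `correlation_suite` from [correlation_suite()].
#' @param alpha significance level on the adjusted p-values.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot correlation_suite
#' @export
autoplot.correlation_suite <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(object,
                      sig = ifelse(.data$p_adjusted <= alpha, "*", ""),
                      family = stats::reorder(.data$family, -.data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$r)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig),
                       vjust = ifelse(df$r >= 0, -0.3, 1.2), size = 6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Pearson r vs %%%s", object$reference[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Null distribution of a gene-group proximity test
#'
#' Histogram of the resampled mean closest distances with the observed
#' value marked.
#'
#' @param object a `cluster_test`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cluster_test
#' @export
autoplot.cluster_test <- function(object, bins = 40, ...) {
  df <- tibble::tibble(null = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("mean closest distance of %s to random sets (bp)",
                  object$group_a),
      y = "samples",
      title = sprintf("%s vs %s: observed %.0f bp, p = %.3g",
                      object$group_a, object$group_b, object$observed,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Percentage heat map of a repertoire table
#'
#' Species-by-family tile map of receptor percentages; zero (null)
#' percentages are drawn grey.
#'
#' @param object a `repertoire_table` from [compute_percentages()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot repertoire_table
#' @export
autoplot.repertoire_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pct = ifelse(.data$percentage == 0, NA_real_,
                                   .data$percentage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$species_id,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  name = "% of searched genes") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
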