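#' Coefficient plot for a fitted activity classifier
#'
#' Median coefficient per feature across the repeated fits, with the
#' across-repeat interquartile range. Features pushing predictions toward
#' "active" (promoter/splice evidence) plot positive; features reflecting
#' full-length transcription (5' CAGE fraction, RNA-seq 5' bias) plot
#' negative.
#'
#' @param object A `tl_model` from [evaluate_repeated()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_model <- function(object, ...) {
  co <- object$coefficients
  df <- tibble(
    term = colnames(co),
    estimate = apply(co, 2, median),
    lo = apply(co, 2, stats::quantile, 0.25),
    hi = apply(co, 2, stats::quantile, 0.75)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median coefficient (min-max scaled features)")
}

#' Enrichment battery plot
#'
#' Bar plot of -log10 p-values from [enrichment_battery()], annotated with
#' the test used per feature.
#'
#' @param enrichment Tibble from [enrichment_battery()].
#' @param alpha Significance line (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = stats::reorder(.data$feature, -.data$p_value),
                               y = -log10(.data$p_value), fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)), fill = "test")
}

#' Feature distribution by reporter activity label
#'
#' Boxplot (numeric features) or proportion bars (binary features) of one
#' feature split by active/nonactive label.
#'
#' @param table Feature-table tibble.
#' @param feature Feature column name.
#' @return A ggplot object.
#' @export
plot_feature_by_label <- function(table, feature) {
  x <- table |>
    filter(.data$label %in% c("active", "nonactive"),
           !is.na(.data[[feature]]))
  v <- x[[feature]]
  if (is.logical(v) || all(v %in% c(0, 1))) {
    df <- x |>
      group_by(.data$label) |>
      summarise(proportion = mean(as.logical(.data[[feature]])), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$proportion)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = NULL, y = paste0("fraction with ", feature))
  } else {
    ggplot2::ggplot(x, ggplot2::aes(x = .data$label, y = .data[[feature]])) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = feature)
  }
}
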