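# Convenience figures. Plotting is a presentation layer only; every number
# shown is computed by the analysis functions.

#' Plot observed/expected X-linkage per bias class
#'
#' Bar chart of the O/E ratio with significance stars, one panel layout per
#' data set when a comparison table is supplied.
#'
#' @param enrichment An [x_enrichment()] tibble, or a [compare_datasets()]
#'   table filtered to the enrichment analysis.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  df <- as_tibble(enrichment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$call, y = .data$oe_ratio)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       vjust = -0.4, size = 5) +
    ggplot2::labs(x = NULL, y = "observed / expected X-linked genes") +
    ggplot2::theme_minimal()
}

#' Plot distance distributions by bias class
#'
#' Boxplots of the distance to the nearest DCC binding site for X-linked
#' genes, split by bias call.
#'
#' @param records Classified table from [classify_sex_bias()].
#' @param distances Distance tibble from [min_site_distance()].
#' @return A ggplot object.
#' @export
plot_site_distance <- function(records, distances) {
  df <- as_tibble(records) |>
    filter(.data$call %in% c("MBG", "FBG", "UBG")) |>
    inner_join(as_tibble(distances)[, c("gene_id", "distance_bp")],
               by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$call,
                                   y = .data$distance_bp / 1000)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "distance to nearest DCC site (kb)") +
    ggplot2::theme_minimal()
}

#' Autoplot method for pipeline reports
#'
#' Shows the O/E enrichment panel of the report.
#'
#' @param object An `xbias_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xbias_report <- function(object, ...) {
  if (is.null(object$enrichment)) {
    abort("report has no enrichment table to plot")
  }
  plot_enrichment(object$enrichment) +
    ggplot2::ggtitle(object$name)
}
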