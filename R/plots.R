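#' Plot sequence-logo column heights
#'
#' Stacked per-base letter heights (frequency x information content, in
#' bits) along the motif; the total bar height is the column's
#' information content, i.e. its degree of conservation.
#'
#' @param logo Tibble from [logo_columns()].
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  long <- tidyr::pivot_longer(
    logo[, c("position", "height_A", "height_C", "height_G", "height_T")],
    -"position", names_to = "base", names_prefix = "height_",
    values_to = "height"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = .data$height, fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "Motif position", y = "Bits", fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot scan hits along promoters
#'
#' One point per hit at its promoter offset, coloured by strand, with
#' dissimilarity on the y axis (low = close to the consensus).
#'
#' @param hits Tibble from [scan_promoters()].
#' @return A ggplot object.
#' @export
plot_scan_hits <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$offset,
                                     y = .data$dissimilarity,
                                     colour = .data$strand)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$promoter_id)) +
    ggplot2::labs(x = "Offset in promoter (bases)",
                  y = "Dissimilarity rate (%)", colour = "Strand") +
    ggplot2::theme_minimal()
}

#' Histogram of best per-promoter dissimilarity
#'
#' Shows the distribution of best dissimilarity across a promoter set
#' with the classification threshold drawn as a dashed line.
#'
#' @param summaries Tibble from [scan_summary()].
#' @param max_dissimilarity Threshold to mark (default 5).
#' @return A ggplot object.
#' @export
plot_dissimilarity <- function(summaries, max_dissimilarity = 5) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$best_dissimilarity)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0,
                            fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = max_dissimilarity,
                        linetype = "dashed", colour = "#D62839") +
    ggplot2::labs(x = "Best dissimilarity rate (%)", y = "Promoters") +
    ggplot2::theme_minimal()
}

#' @rdname log2_rq_test
#' @param object A `log2_rq_test` object.
#' @exportS3Method ggplot2::autoplot
autoplot.log2_rq_test <- function(object, ...) {
  d <- tibble::tibble(stat = c("mean log2 RQ"), value = object$mean_log2_rq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stat, y = .data$value)) +
    ggplot2::geom_col(width = 0.4, fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(y = "log2 RQ", x = NULL,
                  subtitle = sprintf("n = %d, p = %.3g", object$n,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
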