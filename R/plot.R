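# ggplot2 views of the result tables.

#' Barplot of ELD groups
#'
#' Percentage of expressed homoeolog pairs per expression-level-dominance
#' group, labelled with counts.
#'
#' @param x An `eld_summary` (from [summarize_eld()]) or a [classify_eld()]
#'   result.
#' @return A ggplot object.
#' @export
plot_eld_summary <- function(x) {
  if (!inherits(x, "eld_summary")) x <- summarize_eld(x)
  df <- dplyr::mutate(x$group,
                      stratum = factor(.data$stratum, levels = ELD_GROUPS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$percent,
                                   fill = .data$stratum)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "% of expressed pairs",
                  title = "Expression level dominance") +
    ggplot2::theme_minimal()
}

#' Barplot of progeny homoeolog bias
#'
#' @param x A `bias_summary` (from [summarize_bias()]) or a
#'   [classify_bias()] result.
#' @return A ggplot object.
#' @export
plot_bias_summary <- function(x) {
  if (!inherits(x, "bias_summary")) x <- summarize_bias(x)
  df <- dplyr::bind_rows(
    dplyr::mutate(x$progeny, table = "progeny state"),
    dplyr::mutate(x$transition, table = "transition")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$percent,
                                   fill = .data$stratum)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$table), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of expressed pairs",
                  title = "Homoeolog expression bias") +
    ggplot2::theme_minimal()
}

#' Window depth-ratio dot plot per chromosome
#'
#' One point per window (10 kb by default), the visual chromosome-integrity
#' check: intact chromosomes scatter around a constant ratio, lost ones
#' collapse to zero.
#'
#' @param ratios Result of [depth_ratio()].
#' @param expected Optional horizontal reference ratio (e.g. 1).
#' @return A ggplot object.
#' @export
plot_coverage <- function(ratios, expected = NULL) {
  p <- ggplot2::ggplot(ratios,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$ratio,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "depth ratio",
                  title = "Window coverage-depth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(expected)) {
    p <- p + ggplot2::geom_hline(yintercept = expected, linetype = 2)
  }
  p
}
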