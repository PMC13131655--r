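#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dated repeat landscape
#'
#' Stacked bars of repeat-derived bp per age bin, coloured by TE class (or
#' family), mirroring the standard repeat-landscape-through-time figure.
#'
#' @param bins Output of [dated_landscape()].
#' @return A ggplot.
#' @export
plot_landscape <- function(bins) {
  grp <- setdiff(names(bins), c("bin_low", "bin_high", "bp"))[1]
  finite <- filter(bins, is.finite(.data$bin_high))
  ggplot2::ggplot(finite,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$bp / 1e6, fill = .data[[grp]])) +
    ggplot2::geom_col(width = finite$bin_high[1] - finite$bin_low[1]) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (MYA)", y = "Mb", fill = grp,
                  title = "Dated repeat landscape") +
    ggplot2::theme_minimal()
}

#' Plot a TE-insertion rate curve along a root-to-leaf path
#'
#' Step plot of the per-MY TE insertion rate over time, oldest branch on
#' the left.
#'
#' @param steps Output of [rate_curve()].
#' @return A ggplot.
#' @export
plot_rate_curve <- function(steps) {
  long <- tidyr::pivot_longer(
    mutate(steps, .step = row_number()),
    cols = c("age_start", "age_end"), values_to = "age")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$rate,
                                     group = 1)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (MYA)", y = "TE insertions / MY",
                  title = "TE insertion rate along the focal lineage") +
    ggplot2::theme_minimal()
}
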