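# ggplot2 visualisations for fitted results.

#' Plot ROI signal decay with mono-exponential and kurtosis fits
#'
#' @param x A `cdki_curves` object from [one_dim_fit_curves()].
#' @param ... Unused.
#' @return A ggplot (semi-log signal vs b-value).
#' @export
autoplot.cdki_curves <- function(x, ...) {
  long <- tidyr::pivot_longer(x$curves, c("s_mono", "s_dki"),
                              names_to = "fit", values_to = "s")
  long$fit <- c(s_mono = "mono-exponential (low b)",
                s_dki = "1-D kurtosis (all b)")[long$fit]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$b, y = .data$s)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$fit)) +
    ggplot2::geom_point(data = x$points,
                        ggplot2::aes(x = .data$b, y = .data$s)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(b ~ (s/mm^2)), y = "signal (a.u.)",
                  colour = NULL)
}

#' @rdname autoplot.cdki_curves
#' @export
plot_signal_decay <- function(x, ...) autoplot.cdki_curves(x, ...)

#' Plot the fitted-MD decline with maximum b-value
#'
#' @param table A [run_bmax_subset_analysis()] table (or the group table of a
#'   study report).
#' @return A ggplot of mean MD (1e-3 mm^2/s) against bmax.
#' @export
plot_bmax_trend <- function(table) {
  md_col <- if ("md" %in% names(table)) "md" else "md_mean"
  ggplot2::ggplot(table, ggplot2::aes(x = .data$bmax,
                                      y = .data[[md_col]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(b[max] ~ (s/mm^2)),
                  y = expression(MD ~ (10^-3 ~ mm^2/s)))
}

#' Bland-Altman plot for paired subject means
#'
#' @param a,b Paired measurement vectors.
#' @return A ggplot with the mean difference and 95% limits of agreement.
#' @export
plot_bland_altman <- function(a, b) {
  ba <- bland_altman(a, b)
  df <- tibble(avg = (a + b) / 2, diff = a - b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of pair", y = "difference")
}

#' Helix-angle histogram
#'
#' @param ha Vector of helix angles in degrees (or a study report with an
#'   `ha_histogram` table).
#' @param binwidth Bin width in degrees.
#' @return A ggplot histogram over `[-90, 90]`.
#' @export
plot_ha_histogram <- function(ha, binwidth = 5) {
  if (inherits(ha, "cdki_study")) {
    return(ggplot2::ggplot(ha$ha_histogram,
                           ggplot2::aes(x = .data$mid, y = .data$count)) +
             ggplot2::geom_col(width = binwidth) +
             ggplot2::labs(x = "helix angle (deg)", y = "voxels"))
  }
  ggplot2::ggplot(tibble(ha = ha), ggplot2::aes(x = .data$ha)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -90) +
    ggplot2::labs(x = "helix angle (deg)", y = "voxels")
}
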