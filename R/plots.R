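# Diagnostic ggplot2 graphics for the main result types.

#' Plot a linear rate map
#'
#' Raw (steps) and smoothed (line) occupancy-normalised rates per
#' direction.
#'
#' @param map A `linear_rate_map`.
#' @return A ggplot object.
#' @export
plot_linear_rate_map <- function(map) {
  ggplot2::ggplot(map[map$visited, ],
                  ggplot2::aes(x = (.data$lo_cm + .data$hi_cm) / 2)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$rate_raw), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate_smooth), colour = "firebrick") +
    ggplot2::facet_wrap(~direction, ncol = 1) +
    ggplot2::labs(x = "linear position (cm)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_linear_rate_map
#' @param object,... `autoplot` arguments.
#' @export
autoplot.linear_rate_map <- function(object, ...) plot_linear_rate_map(object)

#' Plot a 2D rate map
#'
#' Smoothed firing rate as a colour-coded tile map (unvisited bins
#' blank).
#'
#' @param map A `rate_map_2d`.
#' @return A ggplot object.
#' @export
plot_rate_map_2d <- function(map) {
  ggplot2::ggplot(map[map$visited, ],
                  ggplot2::aes(x = .data$x_lo, y = .data$y_lo,
                               fill = .data$rate_smooth)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Hz") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rate_map_2d
#' @param object,... `autoplot` arguments.
#' @export
autoplot.rate_map_2d <- function(object, ...) plot_rate_map_2d(object)

#' Plot the decoding permutation null
#'
#' Histogram of the label-shuffle null with the observed performance and
#' the 95th percentile marked.
#'
#' @param x A [shuffle_test()] object.
#' @return A ggplot object.
#' @export
plot_shuffle_null <- function(x) {
  df <- tibble(performance = x$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$performance)) +
    ggplot2::geom_histogram(binwidth = 0.05, fill = "grey70",
                            colour = "white", boundary = 0) +
    ggplot2::geom_vline(xintercept = x$q95, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = x$observed, colour = "firebrick") +
    ggplot2::labs(x = "LOOCV performance", y = "shuffles") +
    ggplot2::theme_minimal()
}

#' @rdname plot_shuffle_null
#' @param object,... `autoplot` arguments.
#' @export
autoplot.svm_shuffle_test <- function(object, ...) plot_shuffle_null(object)

#' Plot a peak-density map with its bootstrap null
#'
#' Observed per-bin density with the null median and the one-tailed
#' acceptance band; significant bins highlighted.
#'
#' @param x A [peak_density_bootstrap()] object.
#' @return A ggplot object.
#' @export
plot_peak_density <- function(x) {
  df <- tidy(x)
  df <- df[!is.na(df$density), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_median,
                                      ymax = .data$null_quantile),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$density)) +
    ggplot2::geom_point(data = df[df$significant, ],
                        ggplot2::aes(y = .data$density), colour = "firebrick") +
    ggplot2::labs(x = "spatial bin", y = "peak density") +
    ggplot2::theme_minimal()
}

#' @rdname plot_peak_density
#' @param object,... `autoplot` arguments.
#' @export
autoplot.peak_density_test <- function(object, ...) plot_peak_density(object)
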