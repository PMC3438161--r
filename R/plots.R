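#' Histogram of cell lengths
#'
#' @param stats A `placement_stats` object or a numeric vector of
#'   lengths in microns.
#' @param binwidth Histogram bin width, microns.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(stats, binwidth = 0.5) {
  lens <- if (inherits(stats, "placement_stats")) stats$lengths else stats
  df <- tibble(length_um = lens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_um)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::labs(x = "Cell length (µm)", y = "Frequency") +
    ggplot2::theme_minimal()
}

#' Histogram of normalized septum positions
#'
#' Shades the central band used by [central_fraction()].
#'
#' @param stats A `placement_stats` object or numeric positions.
#' @param band_width Central band width.
#' @return A ggplot object.
#' @export
plot_septum_positions <- function(stats, band_width = 0.2) {
  pos <- if (inherits(stats, "placement_stats")) stats$positions else stats
  if (inherits(stats, "placement_stats")) band_width <- stats$band_width
  df <- tibble(p = pos)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::annotate("rect", xmin = 0.5 - band_width / 2,
                      xmax = 0.5 + band_width / 2,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "blue") +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), fill = "grey35",
                            colour = "white") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Normalized position (pole A → pole B)",
                  y = "Count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.placement_stats <- function(object, ...) {
  if (length(object$positions)) plot_septum_positions(object)
  else plot_length_distribution(object)
}

#' Scatter of placement asymmetry versus differential pole growth
#'
#' @param records Output of [pole_growth_rates()].
#' @return A ggplot object.
#' @export
plot_growth_asymmetry <- function(records) {
  df <- tibble(
    asymmetry = (records$side_a_at_sep - records$side_b_at_sep) /
      (records$side_a_at_sep + records$side_b_at_sep),
    dr = records$r_a - records$r_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$asymmetry, y = .data$dr)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey50", linewidth = 0.4) +
    ggplot2::labs(x = "Relative side-length difference at placement",
                  y = expression(r[a] - r[b] ~ (min^-1))) +
    ggplot2::theme_minimal()
}

#' Length trajectories of tracked cells
#'
#' @param object A `cell_movie_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_movie_analysis <- function(object, ...) {
  df <- dplyr::inner_join(object$tracks, object$masks,
                          by = c("frame", "label"))
  df$time_min <- (df$frame - 1) * object$frame_interval
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$length_um,
                                   group = .data$track_id.x)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Time (min)", y = "Cell length (µm)") +
    ggplot2::theme_minimal()
}
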