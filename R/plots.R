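#' Plot trajectories
#'
#' Draws every track as a path in image coordinates (y axis reversed so
#' the plot matches the video orientation). When a kinematics table is
#' supplied the tracks are coloured by VCL band (`vcl_lower` /
#' `vcl_upper`), mirroring the slow / moderate / fast overlay convention.
#'
#' @param tracks A track tibble.
#' @param kin Optional [measure_kinematics()] output.
#' @param settings Optional [analysis_settings()] (for the VCL bands).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, kin = NULL, settings = NULL) {
  if (!is.null(kin) && !is.null(settings)) {
    band <- dplyr::mutate(kin, vcl_band = dplyr::case_when(
      .data$vcl < settings$vcl_lower ~ "slow",
      .data$vcl <= settings$vcl_upper ~ "moderate",
      TRUE ~ "fast"))
    tracks <- dplyr::left_join(tracks,
                               dplyr::select(band, "track_id", "vcl_band"),
                               by = "track_id")
    p <- ggplot2::ggplot(tracks,
                         ggplot2::aes(.data$x, .data$y,
                                      group = .data$track_id,
                                      colour = .data$vcl_band)) +
      ggplot2::scale_colour_manual(
        values = c(slow = "grey70", moderate = "goldenrod2", fast = "red3"),
        name = "VCL band")
  } else {
    p <- ggplot2::ggplot(tracks,
                         ggplot2::aes(.data$x, .data$y,
                                      group = .data$track_id))
  }
  p + ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Rose diagram of directionality angles
#'
#' Histogram of the instantaneous directionality angles psi in 10-degree
#' bins on a polar axis, the standard way to display the angular
#' distribution a chemotaxis index summarises.
#'
#' @param angles Output of [directionality_angles()] (or a numeric vector
#'   of angles in degrees).
#' @param binwidth Bin width in degrees (default 10, i.e. 36 bins).
#' @return A ggplot object.
#' @export
plot_angle_rose <- function(angles, binwidth = 10) {
  psi <- if (is.data.frame(angles)) angles$psi else angles
  df <- tibble(psi = (psi + 360) %% 360)
  ggplot2::ggplot(df, ggplot2::aes(.data$psi)) +
    ggplot2::geom_histogram(breaks = seq(0, 360, by = binwidth),
                            fill = "steelblue", colour = "white",
                            linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, by = 45),
                                limits = c(0, 360)) +
    ggplot2::labs(x = expression(psi ~ "(degrees)"), y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of a bootstrap O.R. null distribution
#'
#' @param object A `casa_or_null` object.
#' @param ... Unused.
#' @return A ggplot object with the P95 threshold marked.
#' @export
autoplot.casa_or_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$or)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40", colour = "white",
                            linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = object$threshold,
                        colour = "red3", linetype = 2) +
    ggplot2::annotate("text", x = object$threshold, y = Inf,
                      label = sprintf("P95 = %.3f", object$threshold),
                      hjust = -0.1, vjust = 2, colour = "red3", size = 3) +
    ggplot2::labs(x = "O.R. ratio", y = "count") +
    ggplot2::theme_minimal()
}
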