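#' Plot methods
#'
#' `autoplot()` gives the standard display of each result type: angle time
#' series over the normalized stroke cycle for `wing_kinematics` (downstroke
#' shaded), per-station induced-flow speed for `antenna_probe`, and
#' violin summaries of head-relative distance or angles by arrival time for
#' `sampling_volume`.
#'
#' @param object The result object.
#' @param which For `sampling_volume`: `"distance"`, `"h_angle"` or
#'   `"v_angle"`.
#' @param bin_width Arrival-time bin width in cycles for `sampling_volume`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fanflow-autoplot
NULL

downstroke_shade <- function() {
  ggplot2::annotate("rect", xmin = 0, xmax = 0.5, ymin = -Inf, ymax = Inf,
                    alpha = 0.12, fill = "grey20")
}

#' @rdname fanflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.wing_kinematics <- function(object, ...) {
  df <- tidy(object)
  df$series <- ifelse(is.na(df$station), df$angle,
                      sprintf("%s (r/R = %.2f)", df$angle, df$station))
  # feathering is plotted about 90 degrees so all series share an axis range
  df$value_deg <- ifelse(df$angle == "alpha", df$value_deg - 90, df$value_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_hat, y = .data$value_deg,
                                   colour = .data$series)) +
    downstroke_shade() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stroke cycle", y = "angle (deg; feathering - 90)",
                  colour = NULL,
                  title = "Phase-averaged wing angles",
                  subtitle = "shaded: downstroke") +
    ggplot2::theme_minimal()
}

#' @rdname fanflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.antenna_probe <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$t_hat, y = .data$speed_m_s,
                               group = .data$station,
                               colour = .data$arc_frac)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "base → tip") +
    ggplot2::labs(x = "stroke cycle", y = "induced flow speed (m/s)",
                  title = "Flow speed along the antenna") +
    ggplot2::theme_minimal()
}

#' @rdname fanflow-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.sampling_volume <- function(object,
                                     which = c("distance", "h_angle",
                                               "v_angle"),
                                     bin_width = 5, ...) {
  which <- match.arg(which)
  hr <- head_relative_coordinates(object)
  col <- switch(which, distance = "distance_m", h_angle = "h_angle_deg",
                v_angle = "v_angle_deg")
  lab <- switch(which, distance = "distance from head (mm)",
                h_angle = "horizontal angle (deg)",
                v_angle = "vertical angle (deg)")
  df <- tibble::tibble(
    bin = factor(ceiling(hr$cycles_to_arrival / bin_width) * bin_width),
    v = hr[[col]]
  )
  df <- df[!is.na(df$v), ]
  if (which == "distance") df$v <- 1e3 * df$v
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$v)) +
    ggplot2::geom_violin(fill = "grey80", colour = NA, scale = "width") +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 1.6,
                          colour = "white", fill = "black", shape = 21) +
    ggplot2::labs(x = "wingbeats before arrival", y = lab,
                  title = "Sampling volume, head-relative") +
    ggplot2::theme_minimal()
}
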