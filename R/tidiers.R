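#' Tidy methods for fanflow result objects
#'
#' Broom-style accessors. `tidy()` returns the long per-observation tibble
#' behind an object; `glance()` a one-row summary of its headline scalars.
#'
#' @param x A `wing_kinematics`, `antenna_probe`, `particle_trace` or
#'   `sampling_volume` object.
#' @param ... Unused.
#' @return A tibble.
#' @name fanflow-tidiers
NULL

#' @rdname fanflow-tidiers
#' @exportS3Method generics::tidy
tidy.wing_kinematics <- function(x, ...) {
  base <- x$cycle |>
    dplyr::select(dplyr::all_of(c("t_hat", "phi_deg", "theta_deg"))) |>
    tidyr::pivot_longer(-"t_hat", names_to = "angle", values_to = "value_deg") |>
    dplyr::mutate(angle = sub("_deg$", "", .data$angle), station = NA_real_)
  if (!is.null(x$alpha)) {
    base <- dplyr::bind_rows(
      base,
      x$alpha |>
        dplyr::transmute(t_hat = .data$t_hat, angle = "alpha",
                         value_deg = .data$alpha_deg,
                         station = .data$station)
    )
  }
  base
}

#' @rdname fanflow-tidiers
#' @exportS3Method generics::glance
glance.wing_kinematics <- function(x, ...) {
  tibble::tibble(
    frequency_hz = x$frequency_hz,
    amplitude_deg = x$amplitude_deg,
    stroke_plane_deg = x$stroke_plane_deg,
    body_angle_deg = x$body_angle_deg,
    mean_elevation_deg = x$mean_elevation_deg,
    wing_length_m = x$wing_length_m,
    tip_speed_m_s = mean_tip_speed(x$amplitude_deg, x$frequency_hz,
                                   x$wing_length_m),
    n_cycles = x$n_cycles,
    deconflict_rotation_deg = x$deconflict_rotation_deg
  )
}

#' @rdname fanflow-tidiers
#' @exportS3Method generics::tidy
tidy.antenna_probe <- function(x, ...) x$series

#' @rdname fanflow-tidiers
#' @exportS3Method generics::glance
glance.antenna_probe <- function(x, ...) {
  tip <- x$summary[which.max(x$summary$arc_frac), ]
  base <- x$summary[which.min(x$summary$arc_frac), ]
  tibble::tibble(
    n_stations = nrow(x$summary),
    tip_mean_m_s = tip$mean_speed_m_s,
    tip_amplitude_m_s = tip$amplitude_m_s,
    base_mean_m_s = base$mean_speed_m_s,
    dominant = tip$dominant
  )
}

#' @rdname fanflow-tidiers
#' @exportS3Method generics::tidy
tidy.particle_trace <- function(x, ...) x$origins

#' @rdname fanflow-tidiers
#' @exportS3Method generics::tidy
tidy.sampling_volume <- function(x, ...) head_relative_coordinates(x)

#' @rdname fanflow-tidiers
#' @exportS3Method generics::glance
glance.sampling_volume <- function(x, ...) {
  hr <- head_relative_coordinates(x)
  n_h <- sum(!is.na(hr$h_angle_deg))
  tibble::tibble(
    n_origins = nrow(x$origins),
    n_truncated = sum(x$origins$truncated),
    mirrored = x$mirrored,
    median_distance_mm = 1e3 * median(hr$distance_m),
    extent90_deg = if (n_h >= 10)
      angular_extent(hr$h_angle_deg, 0.9, mirrored = x$mirrored)
      else NA_real_,
    anisotropy_p = if (n_h >= 50) anisotropy_test(hr$h_angle_deg)$p.value
      else NA_real_
  )
}
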