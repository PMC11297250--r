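#' Parametric wing-kinematics specification
#'
#' Defines the harmonic flapping model used by the synthetic landmark
#' generator. Defaults are the mean morphological and kinematic parameters of
#' fanning *Bombyx mori* males: wing length 17.3 mm, wingbeat frequency
#' 48.9 Hz, wingbeat amplitude 98 deg, stroke-plane angle 99.5 deg (nearly
#' vertical, tilted slightly posterior), body angle -0.6 deg and mean
#' elevation angle -23.8 deg (the wing always flaps posterior of the stroke
#' plane). The positional angle is a single sinusoid; the feathering angle
#' uses two harmonics with spanwise-growing amplitude to mimic the passive
#' wing twist that is larger during the upstroke.
#'
#' All angular arguments are in degrees (converted to radians internally).
#'
#' @param wing_length_m Wing length R in metres.
#' @param frequency_hz Wingbeat frequency f in Hz.
#' @param amplitude_deg Wingbeat amplitude Phi in degrees (peak-to-peak
#'   excursion of the positional angle).
#' @param stroke_plane_deg Stroke-plane angle beta from horizontal, degrees.
#' @param body_angle_deg Body angle chi (head-up positive), degrees.
#' @param mean_elevation_deg Mean elevation angle theta0, degrees (negative =
#'   posterior of the stroke plane).
#' @param elevation_amplitude_deg Amplitude of the elevation oscillation,
#'   degrees. The elevation oscillates at f in quadrature with the positional
#'   angle (peak deviation at mid-stroke).
#' @param mean_positional_deg Mean positional angle phi0, degrees.
#' @param feathering_amp1_deg,feathering_amp2_deg Tip amplitudes of the first
#'   (f) and second (2f) feathering harmonics, degrees; both scale linearly
#'   with spanwise position r/R.
#' @param feathering_phase1_deg,feathering_phase2_deg Phases of the two
#'   feathering harmonics, degrees.
#' @param phase_deg Global phase offset of the stroke cycle, degrees.
#' @param n_cycles Number of wingbeat cycles to generate.
#' @param frame_rate_hz Sampling rate of the landmark tracks, Hz. Must be at
#'   least 20 f so each cycle is resolved.
#' @param body_length_m Head-tip to abdomen-tip distance, metres.
#' @param antenna_length_m Antenna base-to-tip length, metres.
#' @param pivot_m Numeric length-3: left wing pivot (root) position, metres.
#'
#' @return An object of class `kinematics_spec`.
#' @export
kinematics_spec <- function(wing_length_m = 0.0173,
                            frequency_hz = 48.9,
                            amplitude_deg = 98.0,
                            stroke_plane_deg = 99.5,
                            body_angle_deg = -0.6,
                            mean_elevation_deg = -23.8,
                            elevation_amplitude_deg = 5,
                            mean_positional_deg = 0,
                            feathering_amp1_deg = 25,
                            feathering_amp2_deg = 10,
                            feathering_phase1_deg = 90,
                            feathering_phase2_deg = 0,
                            phase_deg = 0,
                            n_cycles = 4,
                            frame_rate_hz = 2000,
                            body_length_m = 0.03,
                            antenna_length_m = 0.008,
                            pivot_m = c(0, 0.004, 0.012)) {
  spec <- structure(
    list(
      wing_length_m = wing_length_m,
      frequency_hz = frequency_hz,
      amplitude_deg = amplitude_deg,
      stroke_plane_deg = stroke_plane_deg,
      body_angle_deg = body_angle_deg,
      mean_elevation_deg = mean_elevation_deg,
      elevation_amplitude_deg = elevation_amplitude_deg,
      mean_positional_deg = mean_positional_deg,
      feathering_amp1_deg = feathering_amp1_deg,
      feathering_amp2_deg = feathering_amp2_deg,
      feathering_phase1_deg = feathering_phase1_deg,
      feathering_phase2_deg = feathering_phase2_deg,
      phase_deg = phase_deg,
      n_cycles = n_cycles,
      frame_rate_hz = frame_rate_hz,
      body_length_m = body_length_m,
      antenna_length_m = antenna_length_m,
      pivot_m = pivot_m
    ),
    class = "kinematics_spec"
  )
  validate_kinematics_spec(spec)
  spec
}

validate_kinematics_spec <- function(spec) {
  if (!is.numeric(spec$wing_length_m) || spec$wing_length_m <= 0) {
    abort("invalid kinematics_spec: wing_length_m must be > 0",
          class = "fanflow_config_error")
  }
  if (spec$frequency_hz <= 0) {
    abort("invalid kinematics_spec: frequency_hz must be > 0",
          class = "fanflow_config_error")
  }
  if (spec$amplitude_deg <= 0 || spec$amplitude_deg >= 180) {
    abort("invalid kinematics_spec: amplitude_deg must be in (0, 180)",
          class = "fanflow_config_error")
  }
  if (spec$frame_rate_hz < 20 * spec$frequency_hz) {
    abort(paste0(
      "invalid kinematics_spec: frame_rate_hz (", spec$frame_rate_hz,
      ") must be at least 20 * frequency_hz so each cycle is resolved"
    ), class = "fanflow_config_error")
  }
  if (spec$n_cycles < 1) {
    abort("invalid kinematics_spec: n_cycles must be >= 1",
          class = "fanflow_config_error")
  }
  if (length(spec$pivot_m) != 3) {
    abort("invalid kinematics_spec: pivot_m must be length 3",
          class = "fanflow_config_error")
  }
  invisible(spec)
}

#' @export
print.kinematics_spec <- function(x, ...) {
  cat("<kinematics_spec>\n")
  cat(sprintf("  R = %.1f mm, f = %.1f Hz, Phi = %.1f deg\n",
              1e3 * x$wing_length_m, x$frequency_hz, x$amplitude_deg))
  cat(sprintf("  beta = %.1f deg, chi = %.1f deg, theta0 = %.1f deg\n",
              x$stroke_plane_deg, x$body_angle_deg, x$mean_elevation_deg))
  cat(sprintf("  %d cycles at %g fps\n", x$n_cycles, x$frame_rate_hz))
  invisible(x)
}

#' Pinhole camera model
#'
#' @param focal_px Focal length in pixels (same for x and y).
#' @param center_px Principal point (cx, cy) in pixels.
#' @param position_m Camera centre in world coordinates, metres.
#' @param look_at_m World point on the optical axis.
#' @param up Approximate up direction for the image vertical.
#' @param image_size_px Image size (width, height) in pixels.
#'
#' @return Object of class `camera_model` with intrinsic matrix `K`,
#'   world-to-camera rotation `R` and translation `t`.
#' @export
camera_model <- function(focal_px = 2000,
                         center_px = c(512, 512),
                         position_m = c(0.5, 0, 0.1),
                         look_at_m = c(0, 0, 0.02),
                         up = c(0, 0, 1),
                         image_size_px = c(1024, 1024)) {
  K <- matrix(c(focal_px, 0, center_px[1],
                0, focal_px, center_px[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  z_axis <- look_at_m - position_m
  if (vnorm(z_axis) == 0) {
    abort("camera_model: position and look_at coincide",
          class = "fanflow_config_error")
  }
  z_axis <- z_axis / vnorm(z_axis)
  x_axis <- pracma_cross(z_axis, up)
  if (vnorm(x_axis) < 1e-12) {
    abort("camera_model: up direction parallel to optical axis",
          class = "fanflow_config_error")
  }
  x_axis <- x_axis / vnorm(x_axis)
  y_axis <- pracma_cross(z_axis, x_axis)
  R <- rbind(x_axis, y_axis, z_axis)
  dimnames(R) <- NULL
  t <- -as.vector(R %*% position_m)
  structure(
    list(K = K, R = R, t = t, image_size_px = image_size_px),
    class = "camera_model"
  )
}

# cross product (kept local; avoids pulling a package for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Analytic flow-field specification
#'
#' Describes an analytic incompressible velocity field to be sampled onto a
#' structured grid as a stack of time snapshots over one period. Available
#' kinds:
#'
#' * `uniform`: constant velocity `speed_m_s` everywhere.
#' * `point_sink`: radial inflow toward `center_m` with volumetric strength
#'   `strength` (m^3/s), speed Q/(4 pi d^2).
#' * `rankine_vortex`: solid-body core of radius `core_radius_m` around a
#'   vertical axis through `center_m`, circulation `strength` (m^2/s),
#'   irrotational 1/r exterior.
#' * `pulsed_jet`: Gaussian round jet along `axis` through `center_m`, speed
#'   modulated as (1 + sin(2 pi t/T))/2; not divergence-free.
#' * `flapping_dipole`: potential dipole at `center_m` oriented along `axis`
#'   with strength modulated sinusoidally at the pulsation frequency;
#'   divergence-free away from the singular point.
#'
#' @param kind One of the kinds above.
#' @param speed_m_s Velocity vector for `uniform`, or peak speed scalar for
#'   `pulsed_jet`.
#' @param strength Sink strength (m^3/s), circulation (m^2/s), or dipole
#'   strength (m^3/s) depending on kind.
#' @param center_m Location of the singular point / jet origin.
#' @param axis Axis direction for jets, vortices and dipoles.
#' @param core_radius_m Rankine core radius.
#' @param jet_radius_m Gaussian 1/e radius of the pulsed jet.
#' @param frequency_hz Pulsation frequency (sets the period T = 1/f).
#' @param box_min_m,box_max_m Domain corners, metres.
#' @param spacing_m Grid spacing (scalar, isotropic), metres.
#' @param snapshots_per_cycle Number of snapshots over one period, >= 4.
#'
#' @return Object of class `analytic_flow_spec`; `$evaluate(points, time)`
#'   returns an n x 3 velocity matrix.
#' @export
analytic_flow_spec <- function(kind = c("uniform", "point_sink",
                                        "rankine_vortex", "pulsed_jet",
                                        "flapping_dipole"),
                               speed_m_s = c(0.3, 0, 0),
                               strength = 1e-6,
                               center_m = c(0, 0, 0),
                               axis = c(1, 0, 0),
                               core_radius_m = 0.01,
                               jet_radius_m = 0.01,
                               frequency_hz = 48.9,
                               box_min_m = c(-0.05, -0.05, -0.05),
                               box_max_m = c(0.05, 0.05, 0.05),
                               spacing_m = 0.005,
                               snapshots_per_cycle = 50) {
  kind <- match.arg(kind)
  if (spacing_m <= 0) {
    abort("analytic_flow_spec: spacing_m must be > 0",
          class = "fanflow_config_error")
  }
  if (snapshots_per_cycle < 4) {
    abort("analytic_flow_spec: snapshots_per_cycle must be >= 4",
          class = "fanflow_config_error")
  }
  if (any(box_max_m <= box_min_m)) {
    abort("analytic_flow_spec: box_max_m must exceed box_min_m",
          class = "fanflow_config_error")
  }
  axis <- axis / vnorm(axis)
  period_s <- 1 / frequency_hz
  steady <- kind %in% c("uniform", "point_sink", "rankine_vortex")

  evaluate <- switch(
    kind,
    uniform = function(points, time = 0) {
      matrix(rep(speed_m_s, each = nrow(points)), ncol = 3)
    },
    point_sink = function(points, time = 0) {
      d <- sweep(points, 2, center_m)
      r2 <- rowSums(d^2)
      r <- sqrt(r2)
      coef <- -strength / (4 * pi * pmax(r2 * r, 1e-300))
      d * coef
    },
    rankine_vortex = function(points, time = 0) {
      dx <- points[, 1] - center_m[1]
      dy <- points[, 2] - center_m[2]
      r2 <- dx^2 + dy^2
      r <- sqrt(r2)
      omega <- strength / (2 * pi * core_radius_m^2)
      vtheta_over_r <- ifelse(r <= core_radius_m,
                              omega,
                              strength / (2 * pi * pmax(r2, 1e-300)))
      cbind(-dy * vtheta_over_r, dx * vtheta_over_r, 0)
    },
    pulsed_jet = function(points, time = 0) {
      peak <- if (is.matrix(speed_m_s)) stop() else max(abs(speed_m_s))
      d <- sweep(points, 2, center_m)
      axial <- as.vector(d %*% axis)
      radial2 <- rowSums(d^2) - axial^2
      amp <- peak * (1 + sin(2 * pi * time / period_s)) / 2
      profile <- exp(-radial2 / jet_radius_m^2) / (1 + (axial / (4 * jet_radius_m))^2)
      outer(amp * profile, axis)
    },
    flapping_dipole = function(points, time = 0) {
      d <- sweep(points, 2, center_m)
      r2 <- rowSums(d^2)
      r <- sqrt(pmax(r2, 1e-300))
      rhat <- d / r
      m <- strength * sin(2 * pi * time / period_s)
      mdotr <- as.vector(rhat %*% axis)
      coef <- m / (4 * pi * r^3)
      coef * (3 * mdotr * rhat - matrix(rep(axis, each = nrow(points)), ncol = 3))
    }
  )

  structure(
    list(kind = kind, speed_m_s = speed_m_s, strength = strength,
         center_m = center_m, axis = axis, core_radius_m = core_radius_m,
         jet_radius_m = jet_radius_m, frequency_hz = frequency_hz,
         period_s = period_s, box_min_m = box_min_m, box_max_m = box_max_m,
         spacing_m = spacing_m, snapshots_per_cycle = snapshots_per_cycle,
         steady = steady, evaluate = evaluate),
    class = "analytic_flow_spec"
  )
}

#' Wing morphology
#'
#' Elliptic planform with thickness 1% of wing length and an elliptical
#' cross-section, the convention used for moth wing models.
#'
#' @param wing_length_m Wing length R, metres.
#' @param mean_chord_m Mean chord length, metres.
#' @param thickness_ratio Thickness / wing length, default 0.01.
#' @return Object of class `wing_morphology` with a closed planform polyline.
#' @export
wing_morphology <- function(wing_length_m = 0.0173,
                            mean_chord_m = 0.0086,
                            thickness_ratio = 0.01) {
  if (wing_length_m <= 0 || mean_chord_m <= 0) {
    abort("wing_morphology: wing_length_m and mean_chord_m must be > 0",
          class = "fanflow_config_error")
  }
  # elliptic planform with the requested mean chord: c(r) = c0 sqrt(1-(r/R)^2),
  # mean chord of a half-ellipse is (pi/4) c0
  c0 <- mean_chord_m * 4 / pi
  r <- seq(0, wing_length_m, length.out = 25)
  half <- (c0 / 2) * sqrt(pmax(0, 1 - (r / wing_length_m)^2))
  contour <- rbind(
    cbind(r, half),
    cbind(rev(r), -rev(half))
  )
  structure(
    list(wing_length_m = wing_length_m, mean_chord_m = mean_chord_m,
         thickness_ratio = thickness_ratio, contour = contour),
    class = "wing_morphology"
  )
}

#' Fluid constants for air and bombykol
#'
#' Defaults are the kinematic viscosity of air and the diffusion coefficient
#' of bombykol in air at 20 degrees C and 101.3 kPa.
#'
#' @param kinematic_viscosity_m2_s Kinematic viscosity nu, m^2/s.
#' @param diffusion_coefficient_m2_s Molecular diffusivity D, m^2/s.
#' @return Object of class `fluid_constants`.
#' @export
fluid_constants <- function(kinematic_viscosity_m2_s = 1.5e-5,
                            diffusion_coefficient_m2_s = 2.5e-6) {
  if (kinematic_viscosity_m2_s <= 0 || diffusion_coefficient_m2_s <= 0) {
    abort("fluid_constants: both constants must be > 0",
          class = "fanflow_config_error")
  }
  structure(
    list(kinematic_viscosity_m2_s = kinematic_viscosity_m2_s,
         diffusion_coefficient_m2_s = diffusion_coefficient_m2_s),
    class = "fluid_constants"
  )
}

#' Virtual antenna
#'
#' A straight line of probe/release stations standing in for the physical
#' antenna (which is not modelled as a flow obstacle). Stations are equally
#' spaced from base to tip; the default count is 21.
#'
#' @param base_m,tip_m 3D end points, metres.
#' @param n_stations Number of stations, >= 2.
#' @return Object of class `virtual_antenna`; `$stations` is an n x 3 matrix.
#' @export
virtual_antenna <- function(base_m = c(0.012, 0.004, 0.016),
                            tip_m = c(0.018, 0.008, 0.020),
                            n_stations = 21) {
  if (all(base_m == tip_m)) {
    abort("virtual_antenna: base and tip coincide",
          class = "fanflow_config_error")
  }
  if (n_stations < 2) {
    abort("virtual_antenna: n_stations must be >= 2",
          class = "fanflow_config_error")
  }
  frac <- seq(0, 1, length.out = n_stations)
  stations <- outer(frac, tip_m - base_m) +
    matrix(rep(base_m, each = n_stations), ncol = 3)
  structure(
    list(base_m = base_m, tip_m = tip_m, n_stations = n_stations,
         stations = stations),
    class = "virtual_antenna"
  )
}

#' Particle-tracing configuration
#'
#' Defaults mirror the study protocol: particles are released from 21 antenna
#' stations at 21 equally spaced phases of the wingbeat cycle and advected
#' backward with 500 explicit-Euler steps per wingbeat for 40 cycles of the
#' periodic flow.
#'
#' @param n_release_phases Release phases per cycle.
#' @param steps_per_cycle Integration steps per wingbeat.
#' @param n_cycles Number of wingbeat cycles to trace back.
#' @param integrator `"euler"` (the reference advection rule: displacement =
#'   velocity x time step) or `"rk4"` for convergence checks.
#' @param out_of_domain `"truncate"` (stop and flag a trajectory leaving the
#'   grid box; default for tracing) or `"freeze"` (clamp to the boundary).
#' @param record `"cycles"` keeps origin positions at whole-cycle offsets
#'   only; `"full"` keeps every step (memory grows accordingly).
#' @return Object of class `trace_config`.
#' @export
trace_config <- function(n_release_phases = 21,
                         steps_per_cycle = 500,
                         n_cycles = 40,
                         integrator = c("euler", "rk4"),
                         out_of_domain = c("truncate", "freeze"),
                         record = c("cycles", "full")) {
  integrator <- match.arg(integrator)
  out_of_domain <- match.arg(out_of_domain)
  record <- match.arg(record)
  if (n_release_phases < 1 || steps_per_cycle < 1 || n_cycles < 1) {
    abort("trace_config: all counts must be >= 1",
          class = "fanflow_config_error")
  }
  structure(
    list(n_release_phases = n_release_phases,
         steps_per_cycle = steps_per_cycle,
         n_cycles = n_cycles,
         integrator = integrator,
         out_of_domain = out_of_domain,
         record = record),
    class = "trace_config"
  )
}
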