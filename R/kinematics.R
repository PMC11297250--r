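#' Body angle from head and abdomen tips
#'
#' Signed angle between the horizontal plane and the line connecting the head
#' and abdomen tips, positive when the head is above the abdomen. Range
#' (-pi/2, pi/2].
#'
#' @param head_tip,abdomen_tip Numeric length-3 points (metres).
#' @return Angle in radians.
#' @export
body_angle <- function(head_tip, abdomen_tip) {
  d <- head_tip - abdomen_tip
  if (vnorm(d) == 0) {
    abort("body_angle: head and abdomen tips coincide",
          class = "fanflow_geometry_error")
  }
  atan2(d[3], sqrt(d[1]^2 + d[2]^2))
}

#' Stroke-plane angle from the wingtip path
#'
#' Fits the stroke plane by total least squares (first principal direction)
#' of the wingtip path projected onto the x-z plane, and returns its
#' inclination from horizontal in `[0, pi)`. Total least squares keeps the
#' fit well-posed for near-vertical stroke planes, where regressing z on x is
#' singular. The stroke plane itself is the plane through the wing pivot at
#' this inclination.
#'
#' @param wingtip An n x 3 matrix or data frame of wingtip positions (m).
#' @param pivot Wing pivot (unused by the fit itself, which is invariant
#'   under translation; retained because the plane passes through it).
#' @return Stroke-plane angle in radians, in `[0, pi)`.
#' @export
fit_stroke_plane <- function(wingtip, pivot = NULL) {
  if (is.data.frame(wingtip)) {
    wingtip <- as.matrix(wingtip[, c("x_m", "y_m", "z_m")])
  }
  xz <- wingtip[, c(1, 3), drop = FALSE]
  if (nrow(xz) < 3) {
    abort("fit_stroke_plane: need at least 3 wingtip samples",
          class = "fanflow_geometry_error")
  }
  xz <- sweep(xz, 2, colMeans(xz))
  sv <- svd(xz, nu = 0, nv = 2)
  d <- sv$v[, 1]
  ang <- atan2(d[2], d[1])
  ang %% pi
}

#' Positional and elevation angles of the wingtip
#'
#' The elevation angle theta is the signed angle between the pivot-to-tip
#' vector and the stroke plane (negative posterior of the plane); the
#' positional angle phi is the angle of the in-plane projection from the
#' horizontal, measured within the stroke plane. When the pivot-to-tip
#' vector is normal to the stroke plane, phi is undefined: the sample is
#' returned with `phi = NA` and `degenerate = TRUE` so it can be excluded
#' from averaging.
#'
#' @param tip An n x 3 matrix (or length-3 vector) of wingtip positions (m).
#' @param pivot Length-3 wing pivot (m).
#' @param beta Stroke-plane angle, radians.
#' @param side `+1` for the left wing (lateral axis +y), `-1` for the right.
#' @return A tibble with columns `phi`, `theta` (radians) and `degenerate`.
#' @export
positional_elevation <- function(tip, pivot, beta, side = 1) {
  if (is.null(dim(tip))) tip <- matrix(tip, ncol = 3)
  if (is.data.frame(tip)) tip <- as.matrix(tip[, c("x_m", "y_m", "z_m")])
  v <- sweep(tip, 2, pivot)
  nv <- sqrt(rowSums(v^2))
  if (any(nv == 0)) {
    abort("positional_elevation: wingtip coincides with pivot",
          class = "fanflow_geometry_error")
  }
  f <- stroke_frame(beta)
  lat <- c(0, side, 0)
  comp_n <- as.vector(v %*% f$n)
  comp_s <- as.vector(v %*% f$s)
  comp_l <- as.vector(v %*% lat)
  theta <- asin(pmin(1, pmax(-1, comp_n / nv)))
  in_plane <- sqrt(comp_s^2 + comp_l^2)
  degenerate <- in_plane < 1e-12 * nv
  phi <- ifelse(degenerate, NA_real_, atan2(comp_s, comp_l))
  tibble::tibble(phi = phi, theta = theta, degenerate = degenerate)
}

#' Sectional wing-velocity components
#'
#' Relative wing speed parallel (`v_h`) and perpendicular (`v_v`) to the wing
#' cross-section at spanwise location `r`:
#' \deqn{v_h = r(-\dot\phi \cos\alpha \cos\theta + \dot\theta \sin\alpha)}
#' \deqn{v_v = r(-\dot\theta \cos\alpha + \dot\phi \cos\theta \sin\alpha)}
#'
#' @param r Spanwise location, metres.
#' @param phi_dot,theta_dot Angular velocities, rad/s.
#' @param alpha Feathering angle, radians.
#' @param theta Elevation angle, radians.
#' @return A tibble with columns `v_h`, `v_v` (m/s).
#' @export
wing_velocity_components <- function(r, phi_dot, theta_dot, alpha, theta) {
  tibble::tibble(
    v_h = r * (-phi_dot * cos(alpha) * cos(theta) + theta_dot * sin(alpha)),
    v_v = r * (-theta_dot * cos(alpha) + phi_dot * cos(theta) * sin(alpha))
  )
}

#' Angle of attack from sectional velocity components
#'
#' \deqn{AoA = \arccos\left(v_h / \sqrt{v_h^2 + v_v^2}\right) \in [0, \pi]}
#'
#' With `fold = TRUE` values above pi/2 are mapped to `pi - AoA`, giving the
#' geometric incidence in `[0, pi/2]` regardless of which face of the section
#' meets the flow (the convention used for plotting). Zero-speed samples are
#' undefined and returned as `NA`.
#'
#' @param v_h,v_v Sectional velocity components, m/s.
#' @param fold Fold to `[0, pi/2]`?
#' @return Angle of attack in radians (`NA` where `v_h = v_v = 0`).
#' @export
angle_of_attack <- function(v_h, v_v, fold = FALSE) {
  sp <- sqrt(v_h^2 + v_v^2)
  aoa <- ifelse(sp == 0, NA_real_, acos(pmin(1, pmax(-1, v_h / sp))))
  if (fold) aoa <- ifelse(!is.na(aoa) & aoa > pi / 2, pi - aoa, aoa)
  aoa
}

#' Mean wingtip speed, Reynolds number and Schmidt number
#'
#' `mean_tip_speed()` is the mean wingtip speed 2 Phi f R (Phi in radians
#' inside the formula; the argument is in degrees, the reporting unit).
#' `reynolds_number()` uses it as the representative speed with the mean
#' chord as representative length: Re = 2 Phi f R c_m / nu.
#' `schmidt_number()` is the ratio of momentum to mass diffusion nu / D.
#'
#' @param amplitude_deg Wingbeat amplitude Phi, degrees.
#' @param frequency_hz Wingbeat frequency f, Hz.
#' @param wing_length_m Wing length R, metres.
#' @param mean_chord_m Mean chord c_m, metres.
#' @param fluids A [fluid_constants()] object.
#' @return A single number: m/s for `mean_tip_speed()`, dimensionless
#'   otherwise.
#' @export
mean_tip_speed <- function(amplitude_deg, frequency_hz, wing_length_m) {
  2 * deg2rad(amplitude_deg) * frequency_hz * wing_length_m
}

#' @rdname mean_tip_speed
#' @export
reynolds_number <- function(amplitude_deg, frequency_hz, wing_length_m,
                            mean_chord_m, fluids = fluid_constants()) {
  mean_tip_speed(amplitude_deg, frequency_hz, wing_length_m) *
    mean_chord_m / fluids$kinematic_viscosity_m2_s
}

#' @rdname mean_tip_speed
#' @export
schmidt_number <- function(fluids = fluid_constants()) {
  fluids$kinematic_viscosity_m2_s / fluids$diffusion_coefficient_m2_s
}

# ---- cycle handling ----------------------------------------------------

# spectral derivative of a periodic series sampled uniformly over period T
spectral_deriv <- function(y, period) {
  n <- length(y)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  if (n %% 2 == 0) k[n / 2 + 1] <- 0  # drop Nyquist for the derivative
  Y <- fft(y)
  Re(fft(1i * 2 * pi * k / period * Y, inverse = TRUE)) / n
}

# low-pass filter keeping harmonics at or below `cutoff_hz`
fft_lowpass <- function(y, dt, cutoff_hz) {
  n <- length(y)
  freq <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / (n * dt)
  Y <- fft(y)
  Y[abs(freq) > cutoff_hz] <- 0
  Re(fft(Y, inverse = TRUE)) / n
}

# refine the location of a discrete extremum by quadratic interpolation
refine_peak <- function(y, i, t, sign = 1) {
  if (i <= 1 || i >= length(y)) return(t[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(t[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  t[i] + delta * (t[2] - t[1])
}

# detect downstroke starts (maxima of phi) on a low-pass-filtered series;
# returns refined peak times
detect_cycle_starts <- function(time_s, phi) {
  dt <- time_s[2] - time_s[1]
  n <- length(phi)
  # first estimate of f from the dominant non-zero spectral peak
  y <- phi - mean(phi)
  Y <- Mod(fft(y))[2:floor(n / 2)]
  f0 <- which.max(Y) / (n * dt)
  sm <- fft_lowpass(phi, dt, 3 * f0)
  idx <- which(diff(sign(diff(sm))) == -2) + 1
  idx <- idx[idx > 1 & idx < n]
  if (length(idx) < 2) {
    abort("average_cycles: fewer than one complete wingbeat cycle detected",
          class = "fanflow_data_error")
  }
  vapply(idx, function(i) refine_peak(sm, i, time_s), numeric(1))
}

#' Phase-average wingbeat cycles
#'
#' Segments per-frame angle series into wingbeat cycles delimited at maxima
#' of the positional angle (downstroke start, so the downstroke occupies
#' normalized time t_hat in [0, 0.5)), resamples each cycle onto a common
#' t_hat grid by spline interpolation, and averages across cycles (and across
#' sides/groups, e.g. the left and the mirrored right wing).
#'
#' @param frames A data frame with columns `time_s`, a grouping column
#'   `side` (optional), and one or more numeric angle columns.
#' @param phi_col Name of the positional-angle column used for segmentation.
#' @param n_grid Points of the common t_hat grid.
#' @return A list with `cycle` (tibble: `t_hat` + averaged angle columns),
#'   `frequency_hz` (from the mean cycle duration), `n_cycles` averaged, and
#'   `per_cycle` (tibble of all resampled cycles before averaging).
#' @export
average_cycles <- function(frames, phi_col = "phi_deg", n_grid = 200) {
  if (!phi_col %in% names(frames)) {
    abort(paste0("average_cycles: no column '", phi_col, "'"),
          class = "fanflow_data_error")
  }
  if (!"side" %in% names(frames)) frames$side <- "C"
  angle_cols <- setdiff(names(frames)[vapply(frames, is.numeric, TRUE)],
                        "time_s")
  t_hat <- seq(0, 1, length.out = n_grid + 1)[seq_len(n_grid)]
  groups <- split(frames, frames$side)
  all_cycles <- list()
  freqs <- c()
  for (g in groups) {
    g <- g[order(g$time_s), ]
    starts <- detect_cycle_starts(g$time_s, g[[phi_col]])
    freqs <- c(freqs, 1 / diff(starts))
    for (j in seq_len(length(starts) - 1)) {
      t0 <- starts[j]
      t1 <- starts[j + 1]
      tq <- t0 + t_hat * (t1 - t0)
      res <- tibble::tibble(t_hat = t_hat)
      for (col in angle_cols) {
        res[[col]] <- stats::spline(g$time_s, g[[col]], xout = tq,
                                    method = "fmm")$y
      }
      res$side <- g$side[1]
      res$cycle <- j
      all_cycles[[length(all_cycles) + 1]] <- res
    }
  }
  per_cycle <- dplyr::bind_rows(all_cycles)
  cycle <- per_cycle |>
    dplyr::group_by(.data$t_hat) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(angle_cols), mean),
                     .groups = "drop")
  list(
    cycle = cycle,
    frequency_hz = mean(freqs),
    n_cycles = length(all_cycles),
    per_cycle = per_cycle
  )
}

# peak-to-peak excursion of a periodic sampled series, with quadratic
# refinement of both extrema
series_excursion <- function(y, t) {
  i_max <- which.max(y)
  i_min <- which.min(y)
  refine_val <- function(i) {
    if (i <= 1 || i >= length(y)) return(y[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom == 0) return(y[i])
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta
  }
  refine_val(i_max) - refine_val(i_min)
}

#' Reconstruct wing kinematics from landmark tracks
#'
#' Full kinematic reconstruction: wing pivots from the wing-root landmarks,
#' stroke-plane angle by total-least-squares fit of the wingtip path in the
#' x-z plane, per-frame positional/elevation angles, body angle from the
#' head/abdomen axis, cycle segmentation at downstroke starts,
#' phase-averaging over all wingbeats and over the left and right wings, and
#' (when contour landmarks are present) the spanwise feathering-angle series
#' at the requested stations. Angular velocities of the averaged periodic
#' series are computed by spectral differentiation.
#'
#' @param track A `landmark_track` tibble (see [generate_landmarks()] /
#'   [read_landmarks()]).
#' @param stations Spanwise stations (fractions of R) for the feathering and
#'   angle-of-attack series.
#' @param n_grid Size of the normalized-time grid for the averaged cycle.
#' @return An object of class `wing_kinematics`: a list with the averaged
#'   `cycle` tibble (`t_hat`, `phi_deg`, `theta_deg`, `phi_dot_rad_s`,
#'   `theta_dot_rad_s`), `alpha` (long tibble `t_hat`, `station`,
#'   `alpha_deg`, when contours are available), and scalars
#'   `stroke_plane_deg`, `body_angle_deg`, `frequency_hz`, `amplitude_deg`,
#'   `mean_elevation_deg`, `wing_length_m`, `pivot_m`, `n_cycles`.
#' @export
reconstruct_kinematics <- function(track, stations = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                   n_grid = 200) {
  need <- c("wing_tip", "wing_root", "head_tip", "abdomen_tip")
  have <- unique(track$landmark)
  if (!all(need %in% have)) {
    abort(paste0("reconstruct_kinematics: track lacks landmark(s): ",
                 paste(setdiff(need, have), collapse = ", ")),
          class = "fanflow_data_error")
  }

  heads <- track[track$landmark == "head_tip", ]
  abds <- track[track$landmark == "abdomen_tip", ]
  chi <- mean(vapply(seq_len(nrow(heads)), function(i) {
    body_angle(as.numeric(heads[i, c("x_m", "y_m", "z_m")]),
               as.numeric(abds[i, c("x_m", "y_m", "z_m")]))
  }, numeric(1)))

  sides <- intersect(c("L", "R"), unique(track$side))
  per_side <- list()
  betas <- c()
  pivots <- list()
  Rlens <- c()
  for (sd in sides) {
    sgn <- if (sd == "L") 1 else -1
    tips <- track[track$landmark == "wing_tip" & track$side == sd, ]
    tips <- tips[order(tips$time_s), ]
    roots <- track[track$landmark == "wing_root" & track$side == sd, ]
    pivot <- colMeans(as.matrix(roots[, c("x_m", "y_m", "z_m")]))
    tipm <- as.matrix(tips[, c("x_m", "y_m", "z_m")])

    # provisional stroke plane for segmentation, refit on complete cycles
    beta0 <- fit_stroke_plane(tipm, pivot)
    pe0 <- positional_elevation(tipm, pivot, beta0, sgn)
    starts <- detect_cycle_starts(tips$time_s, pe0$phi)
    in_cycles <- tips$time_s >= starts[1] & tips$time_s <= tail(starts, 1)
    beta <- fit_stroke_plane(tipm[in_cycles, , drop = FALSE], pivot)
    pe <- positional_elevation(tipm, pivot, beta, sgn)

    betas <- c(betas, beta)
    pivots[[sd]] <- pivot
    Rlens <- c(Rlens, mean(sqrt(rowSums(sweep(tipm, 2, pivot)^2))))

    df <- tibble::tibble(
      time_s = tips$time_s, side = sd,
      phi_deg = rad2deg(pe$phi), theta_deg = rad2deg(pe$theta)
    )
    df <- df[!pe$degenerate, ]

    # feathering from 3D contour pairs (leading/trailing edge per station)
    cont <- track[grepl("^contour_", track$landmark) & track$side == sd, ]
    if (nrow(cont) > 0) {
      alpha_df <- contour_alpha(cont, pivot, beta, sgn, pe, tips$time_s,
                                Rlens[length(Rlens)], stations)
      df <- dplyr::left_join(df, alpha_df, by = "time_s")
    }
    per_side[[sd]] <- df
  }
  frames <- dplyr::bind_rows(per_side)
  beta <- mean(betas)

  avg <- average_cycles(frames, phi_col = "phi_deg", n_grid = n_grid)
  cyc <- avg$cycle
  f_hz <- avg$frequency_hz
  period <- 1 / f_hz
  cyc$phi_dot_rad_s <- spectral_deriv(deg2rad(cyc$phi_deg), period)
  cyc$theta_dot_rad_s <- spectral_deriv(deg2rad(cyc$theta_deg), period)

  alpha_long <- NULL
  acol <- grep("^alpha_", names(cyc), value = TRUE)
  if (length(acol) > 0) {
    alpha_long <- cyc |>
      dplyr::select(dplyr::all_of(c("t_hat", acol))) |>
      tidyr::pivot_longer(dplyr::all_of(acol), names_to = "station",
                          values_to = "alpha_deg") |>
      dplyr::mutate(station = as.numeric(sub("^alpha_", "", .data$station)) / 100)
  }

  structure(
    list(
      cycle = cyc[, c("t_hat", "phi_deg", "theta_deg",
                      "phi_dot_rad_s", "theta_dot_rad_s")],
      alpha = alpha_long,
      stroke_plane_deg = rad2deg(beta),
      body_angle_deg = rad2deg(chi),
      frequency_hz = f_hz,
      amplitude_deg = series_excursion(cyc$phi_deg, cyc$t_hat),
      mean_elevation_deg = mean(cyc$theta_deg),
      wing_length_m = mean(Rlens),
      pivot_m = pivots[[sides[1]]],
      n_cycles = avg$n_cycles,
      deconflict_rotation_deg = 0,
      per_cycle = avg$per_cycle
    ),
    class = "wing_kinematics"
  )
}

# feathering angles from 3D leading/trailing-edge contour pairs: the chord
# direction resolved in the section frame gives alpha directly at each
# contour station; values at the requested stations follow by linear
# interpolation (linear extrapolation beyond the outermost pair)
contour_alpha <- function(cont, pivot, beta, sgn, pe, times, R, stations) {
  cont$pair <- (as.numeric(sub("^contour_", "", cont$landmark)) + 1) %/% 2
  pairs <- sort(unique(cont$pair))
  frac_of_pair <- contour_stations[pairs]
  n_t <- length(times)
  alpha_pair <- matrix(NA_real_, n_t, length(pairs))
  le_all <- cont[as.numeric(sub("^contour_", "", cont$landmark)) %% 2 == 1, ]
  te_all <- cont[as.numeric(sub("^contour_", "", cont$landmark)) %% 2 == 0, ]
  for (jj in seq_along(pairs)) {
    j <- pairs[jj]
    le <- le_all[le_all$pair == j, ]
    te <- te_all[te_all$pair == j, ]
    le <- le[order(le$time_s), ]
    te <- te[order(te$time_s), ]
    d <- as.matrix(le[, c("x_m", "y_m", "z_m")]) -
      as.matrix(te[, c("x_m", "y_m", "z_m")])
    for (i in seq_len(n_t)) {
      fr <- wing_frame(beta, sgn, pe$phi[i], pe$theta[i])
      alpha_pair[i, jj] <- atan2(sum(d[i, ] * fr$e_n), sum(d[i, ] * fr$e_t))
    }
  }
  out <- tibble::tibble(time_s = times)
  for (st in stations) {
    a <- apply(alpha_pair, 1, interp_extrap, x = frac_of_pair, xout = st)
    out[[sprintf("alpha_%d", round(100 * st))]] <- rad2deg(a)
  }
  out
}

# linear interpolation with linear (not constant) extrapolation at the ends
interp_extrap <- function(y, x, xout) {
  if (xout <= x[1]) {
    return(y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout - x[1]))
  }
  k <- length(x)
  if (xout >= x[k]) {
    return(y[k] + (y[k] - y[k - 1]) / (x[k] - x[k - 1]) * (xout - x[k]))
  }
  stats::approx(x, y, xout = xout)$y
}

#' @export
print.wing_kinematics <- function(x, ...) {
  cat("<wing_kinematics>\n")
  cat(sprintf("  f = %.2f Hz, Phi = %.1f deg, beta = %.1f deg\n",
              x$frequency_hz, x$amplitude_deg, x$stroke_plane_deg))
  cat(sprintf("  chi = %.2f deg, mean theta = %.1f deg, R = %.1f mm\n",
              x$body_angle_deg, x$mean_elevation_deg, 1e3 * x$wing_length_m))
  cat(sprintf("  averaged over %d cycles on a %d-point cycle grid\n",
              x$n_cycles, nrow(x$cycle)))
  if (x$deconflict_rotation_deg != 0) {
    cat(sprintf("  sagittal deconfliction rotation: %.2f deg\n",
                x$deconflict_rotation_deg))
  }
  invisible(x)
}

#' Spanwise angle-of-attack series
#'
#' Evaluates the sectional velocity components and the angle of attack at
#' each feathering station of an averaged cycle. Both the raw `[0, 180]` and
#' the folded `[0, 90]` series (in degrees) are returned.
#'
#' @param kin A `wing_kinematics` object with a feathering series.
#' @return A tibble: `t_hat`, `station`, `v_h`, `v_v`, `aoa_deg`,
#'   `aoa_folded_deg`.
#' @export
angle_of_attack_series <- function(kin) {
  if (is.null(kin$alpha)) {
    abort("angle_of_attack_series: kinematics has no feathering series",
          class = "fanflow_data_error")
  }
  df <- dplyr::left_join(kin$alpha, kin$cycle, by = "t_hat")
  vc <- wing_velocity_components(
    r = df$station * kin$wing_length_m,
    phi_dot = df$phi_dot_rad_s,
    theta_dot = df$theta_dot_rad_s,
    alpha = deg2rad(df$alpha_deg),
    theta = deg2rad(df$theta_deg)
  )
  tibble::tibble(
    t_hat = df$t_hat, station = df$station,
    v_h = vc$v_h, v_v = vc$v_v,
    aoa_deg = rad2deg(angle_of_attack(vc$v_h, vc$v_v)),
    aoa_folded_deg = rad2deg(angle_of_attack(vc$v_h, vc$v_v, fold = TRUE))
  )
}
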