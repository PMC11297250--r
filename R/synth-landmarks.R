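# Shared wing-pose model.
#
# For stroke-plane inclination beta the wing is posed in the stroke frame
# (lat, s, n): lat = side * y-hat is the horizontal in-plane direction, s the
# inclined in-plane direction, n the plane normal. The spanwise axis for
# positional angle phi and elevation theta is
#   e_r = cos(theta) (cos(phi) lat + sin(phi) s) + sin(theta) n,
# the in-plane tangent e_t = -sin(phi) lat + cos(phi) s, and the section
# normal e_n = e_r x e_t (equal to side * n at theta = 0). A cross-section at
# spanwise r with feathering alpha has chord direction
#   e_c = cos(alpha) e_t + sin(alpha) e_n,
# so alpha is the angle between the chord and the stroke plane.
wing_frame <- function(beta, side, phi, theta) {
  lat <- c(0, side, 0)
  f <- stroke_frame(beta)
  e_r <- cos(theta) * (cos(phi) * lat + sin(phi) * f$s) + sin(theta) * f$n
  e_t <- -sin(phi) * lat + cos(phi) * f$s
  e_n <- pracma_cross(e_r, e_t)
  list(e_r = e_r, e_t = e_t, e_n = e_n)
}

# leading/trailing-edge points of the section at spanwise fraction `frac`
wing_section_points <- function(pivot, beta, side, phi, theta, alpha,
                                frac, wing_length, chord) {
  fr <- wing_frame(beta, side, phi, theta)
  mid <- pivot + frac * wing_length * fr$e_r
  e_c <- cos(alpha) * fr$e_t + sin(alpha) * fr$e_n
  list(le = mid + (chord / 2) * e_c, te = mid - (chord / 2) * e_c)
}

# elliptic chord profile used for synthetic contours
chord_at <- function(frac, mean_chord) {
  (mean_chord * 4 / pi) * sqrt(pmax(0, 1 - frac^2))
}

contour_stations <- c(0.15, 0.35, 0.55, 0.75, 0.95)

# prescribed angle time series of the harmonic model (radians)
spec_angles <- function(spec, t) {
  w <- 2 * pi * spec$frequency_hz
  ph <- deg2rad(spec$phase_deg)
  list(
    phi = deg2rad(spec$mean_positional_deg) +
      deg2rad(spec$amplitude_deg) / 2 * cos(w * t + ph),
    theta = deg2rad(spec$mean_elevation_deg) +
      deg2rad(spec$elevation_amplitude_deg) * sin(w * t + ph),
    phi_dot = -deg2rad(spec$amplitude_deg) / 2 * w * sin(w * t + ph),
    theta_dot = deg2rad(spec$elevation_amplitude_deg) * w * cos(w * t + ph)
  )
}

# feathering angle (radians) at spanwise fraction frac, time t
spec_alpha <- function(spec, frac, t) {
  w <- 2 * pi * spec$frequency_hz
  ph <- deg2rad(spec$phase_deg)
  deg2rad(90) +
    deg2rad(spec$feathering_amp1_deg) * frac *
      cos(w * t + ph + deg2rad(spec$feathering_phase1_deg)) +
    deg2rad(spec$feathering_amp2_deg) * frac *
      cos(2 * (w * t + ph) + deg2rad(spec$feathering_phase2_deg))
}

#' Generate synthetic landmark tracks
#'
#' Builds the 3D landmark time series that a two-camera high-speed
#' reconstruction would produce for a fanning moth, from the prescribed
#' harmonic kinematics in `spec`: head and abdomen tips, antenna base and tip
#' (left/right), wing root and tip and ten wing-contour points (leading and
#' trailing edge at five spanwise stations) for both wings. With
#' `noise_sd = 0` the tracks are exactly consistent with the prescribed
#' angles; the generating angle series are attached as attribute `"truth"`
#' for recovery tests.
#'
#' @param spec A [kinematics_spec()].
#' @param noise_sd Isotropic Gaussian tracking-noise s.d. in metres, >= 0.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @return A tibble with columns `time_s`, `side` (`L`/`R`/`C`), `landmark`,
#'   `x_m`, `y_m`, `z_m`, of class `landmark_track`, with attributes `truth`
#'   (tibble of generating angles, degrees) and `spec`.
#' @export
generate_landmarks <- function(spec, noise_sd = 0, seed = NULL) {
  validate_kinematics_spec(spec)
  if (noise_sd < 0) {
    abort("generate_landmarks: noise_sd must be >= 0",
          class = "fanflow_config_error")
  }
  n_frames <- ceiling(spec$n_cycles * spec$frame_rate_hz / spec$frequency_hz)
  t <- (seq_len(n_frames) - 1) / spec$frame_rate_hz
  ang <- spec_angles(spec, t)
  beta <- deg2rad(spec$stroke_plane_deg)
  chi <- deg2rad(spec$body_angle_deg)
  R <- spec$wing_length_m
  mean_chord <- 0.5 * R  # planform proportion used for contour synthesis

  body_center <- c(0, 0, spec$pivot_m[3])
  body_dir <- c(cos(chi), 0, sin(chi))
  head_tip <- body_center + (spec$body_length_m / 2) * body_dir
  abdomen_tip <- body_center - (spec$body_length_m / 2) * body_dir

  rows <- list()
  push <- function(time_s, side, landmark, p) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      time_s = time_s, side = side, landmark = landmark,
      x_m = p[1], y_m = p[2], z_m = p[3]
    )
  }

  static_per_side <- function(side_chr, side_sgn) {
    ant_base <- head_tip + c(0.001, side_sgn * 0.002, 0.001)
    ant_dir <- c(0.75, side_sgn * 0.3, 0.55)
    ant_dir <- ant_dir / vnorm(ant_dir)
    ant_tip <- ant_base + spec$antenna_length_m * ant_dir
    list(base = ant_base, tip = ant_tip)
  }
  ant <- list(L = static_per_side("L", +1), R = static_per_side("R", -1))

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    ti <- t[i]
    phi <- ang$phi[i]
    theta <- ang$theta[i]
    out <- list(
      tibble::tibble(time_s = ti, side = "C", landmark = "head_tip",
                     x_m = head_tip[1], y_m = head_tip[2], z_m = head_tip[3]),
      tibble::tibble(time_s = ti, side = "C", landmark = "abdomen_tip",
                     x_m = abdomen_tip[1], y_m = abdomen_tip[2],
                     z_m = abdomen_tip[3])
    )
    for (side_chr in c("L", "R")) {
      sgn <- if (side_chr == "L") 1 else -1
      pivot <- spec$pivot_m * c(1, sgn, 1)
      fr <- wing_frame(beta, sgn, phi, theta)
      tip <- pivot + R * fr$e_r
      out[[length(out) + 1]] <- tibble::tibble(
        time_s = ti, side = side_chr,
        landmark = c("antenna_base", "antenna_tip", "wing_root", "wing_tip"),
        x_m = c(ant[[side_chr]]$base[1], ant[[side_chr]]$tip[1], pivot[1], tip[1]),
        y_m = c(ant[[side_chr]]$base[2], ant[[side_chr]]$tip[2], pivot[2], tip[2]),
        z_m = c(ant[[side_chr]]$base[3], ant[[side_chr]]$tip[3], pivot[3], tip[3])
      )
      k <- 0
      cx <- cy <- cz <- nm <- c()
      for (j in seq_along(contour_stations)) {
        frac <- contour_stations[j]
        alpha <- spec_alpha(spec, frac, ti)
        sec <- wing_section_points(pivot, beta, sgn, phi, theta, alpha,
                                   frac, R, chord_at(frac, mean_chord))
        for (p in list(sec$le, sec$te)) {
          k <- k + 1
          cx <- c(cx, p[1]); cy <- c(cy, p[2]); cz <- c(cz, p[3])
          nm <- c(nm, paste0("contour_", k))
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        time_s = ti, side = side_chr, landmark = nm,
        x_m = cx, y_m = cy, z_m = cz
      )
    }
    frames[[i]] <- dplyr::bind_rows(out)
  }
  track <- dplyr::bind_rows(frames)

  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    n <- nrow(track)
    track$x_m <- track$x_m + rnorm(n, 0, noise_sd)
    track$y_m <- track$y_m + rnorm(n, 0, noise_sd)
    track$z_m <- track$z_m + rnorm(n, 0, noise_sd)
  }

  truth <- tibble::tibble(
    time_s = t,
    phi_deg = rad2deg(ang$phi),
    theta_deg = rad2deg(ang$theta),
    body_angle_deg = spec$body_angle_deg,
    stroke_plane_deg = spec$stroke_plane_deg
  )
  attr(track, "truth") <- truth
  attr(track, "spec") <- spec
  class(track) <- c("landmark_track", class(track))
  track
}

#' Write / read landmark tracks as CSV
#'
#' One row per landmark per frame with columns `time_s`, `side`, `landmark`,
#' `x_m`, `y_m`, `z_m`. `write_landmarks()` can write a JSON sidecar carrying
#' the generating [kinematics_spec()] for recovery tests.
#'
#' @param track A `landmark_track` tibble.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` with the generating spec when present?
#' @return `write_landmarks()` returns `path` invisibly; `read_landmarks()`
#'   returns a `landmark_track` tibble (with the spec re-attached when a
#'   sidecar is found).
#' @export
write_landmarks <- function(track, path, sidecar = TRUE) {
  cols <- c("time_s", "side", "landmark", "x_m", "y_m", "z_m")
  utils::write.csv(as.data.frame(track)[, cols], path, row.names = FALSE)
  spec <- attr(track, "spec")
  if (sidecar && !is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "side", "landmark", "x_m", "y_m", "z_m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("read_landmarks: ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fanflow_format_error")
  }
  track <- tibble::as_tibble(df)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    raw <- jsonlite::read_json(sc, simplifyVector = TRUE)
    spec <- try(do.call(kinematics_spec, raw[names(raw) %in%
                                               names(formals(kinematics_spec))]),
                silent = TRUE)
    if (!inherits(spec, "try-error")) attr(track, "spec") <- spec
  }
  class(track) <- c("landmark_track", class(track))
  track
}
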