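#' Fit spanwise feathering angles from camera contours
#'
#' Recovers the feathering (twist) angle at each spanwise station by posing
#' the model wing with the known positional/elevation angles and a candidate
#' twist profile, reprojecting its section contour points through the
#' calibrated cameras, and minimising the summed squared image distance to
#' the observed 2D contour points. The profile between stations is linear,
#' and a quadratic penalty on second spanwise differences regularises the
#' station values; since the penalty vanishes on any linear twist, a
#' noise-free linear profile is recovered without bias.
#'
#' Frames whose optimiser does not converge are excluded and reported in the
#' `failures` attribute.
#'
#' @param image_tracks Per-camera 2D contour tracks (from
#'   [project_landmarks()]): columns `camera`, `time_s`, `side`, `landmark`
#'   (`contour_<k>`), `u_px`, `v_px`. At least two cameras and four contour
#'   points per camera per frame.
#' @param cameras The calibrated [camera_model()] list.
#' @param angles Tibble with per-frame `time_s`, `phi_deg`, `theta_deg`.
#' @param pivot Wing pivot, metres.
#' @param beta_deg Stroke-plane angle, degrees.
#' @param wing_length_m Wing length R, metres.
#' @param mean_chord_m Mean chord of the elliptic planform, metres.
#' @param stations Spanwise stations (fractions of R) carrying the fitted
#'   twist values; contour pairs are assigned to their generating stations.
#' @param lambda Smoothing weight (px^2 per rad^2 of second difference).
#' @param side Wing side to fit (`"L"` or `"R"`).
#' @return Tibble: `time_s`, `station`, `alpha_deg`; attribute `failures`
#'   lists excluded frames.
#' @export
fit_feathering <- function(image_tracks, cameras, angles, pivot,
                           beta_deg, wing_length_m,
                           mean_chord_m = 0.5 * wing_length_m,
                           stations = contour_stations,
                           lambda = 10, side = "L") {
  if (length(cameras) < 2) {
    abort("fit_feathering: at least 2 cameras are required",
          class = "fanflow_config_error")
  }
  obs <- image_tracks[grepl("^contour_", image_tracks$landmark) &
                        image_tracks$side == side, ]
  if (nrow(obs) == 0) {
    abort("fit_feathering: no contour observations for this side",
          class = "fanflow_data_error")
  }
  beta <- deg2rad(beta_deg)
  sgn <- if (side == "L") 1 else -1
  Ps <- lapply(cameras, camera_P)
  K <- length(stations)

  project_pts <- function(P3, Pmat) {
    uvw <- cbind(P3, 1) %*% t(Pmat)
    uvw[, 1:2] / uvw[, 3]
  }

  # candidate twist at an arbitrary fraction: linear interpolation between
  # stations, constant extrapolation beyond the end stations
  alpha_interp <- function(a, frac) {
    stats::approx(stations, a, xout = frac, rule = 2)$y
  }

  out <- list()
  failures <- c()
  for (i in seq_len(nrow(angles))) {
    ti <- angles$time_s[i]
    phi <- deg2rad(angles$phi_deg[i])
    theta <- deg2rad(angles$theta_deg[i])
    frame_obs <- obs[obs$time_s == ti, ]
    n_per_cam <- table(frame_obs$camera)
    if (length(n_per_cam) < 2 || any(n_per_cam < 4)) {
      failures <- c(failures, ti)
      next
    }
    pair <- (as.numeric(sub("^contour_", "", frame_obs$landmark)) + 1) %/% 2
    frac <- contour_stations[pair]
    is_le <- as.numeric(sub("^contour_", "", frame_obs$landmark)) %% 2 == 1

    objective <- function(a) {
      al <- alpha_interp(a, frac)
      fr <- wing_frame(beta, sgn, phi, theta)
      mid <- matrix(pivot, nrow(frame_obs), 3, byrow = TRUE) +
        outer(frac * wing_length_m, fr$e_r)
      e_c <- outer(cos(al), fr$e_t) + outer(sin(al), fr$e_n)
      half <- chord_at(frac, mean_chord_m) / 2
      P3 <- mid + ifelse(is_le, 1, -1) * half * e_c
      sse <- 0
      for (ci in unique(frame_obs$camera)) {
        rows <- frame_obs$camera == ci
        uv <- project_pts(P3[rows, , drop = FALSE], Ps[[ci]])
        sse <- sse + sum((uv[, 1] - frame_obs$u_px[rows])^2 +
                           (uv[, 2] - frame_obs$v_px[rows])^2)
      }
      if (K >= 3) {
        d2 <- diff(diff(a))
        sse <- sse + lambda * sum(d2^2)
      }
      sse
    }
    fit <- optim(rep(pi / 2, K), objective, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12))
    if (fit$convergence != 0) {
      failures <- c(failures, ti)
      next
    }
    out[[length(out) + 1]] <- tibble::tibble(
      time_s = ti, station = stations, alpha_deg = rad2deg(fit$par)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "failures") <- failures
  res
}
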