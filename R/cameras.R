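#' Project landmark tracks into camera images
#'
#' Pinhole projection of 3D landmark tracks into each camera of a calibrated
#' multi-camera rig, the fixture for triangulation and calibration-error
#' checks.
#'
#' @param track A `landmark_track` tibble (columns `time_s`, `side`,
#'   `landmark`, `x_m`, `y_m`, `z_m`).
#' @param cameras A list of two or more [camera_model()] objects.
#' @return A tibble with columns `camera`, `time_s`, `side`, `landmark`,
#'   `u_px`, `v_px`.
#' @export
project_landmarks <- function(track, cameras) {
  if (length(cameras) < 2) {
    abort("project_landmarks: at least 2 cameras are required",
          class = "fanflow_config_error")
  }
  P <- as.matrix(track[, c("x_m", "y_m", "z_m")])
  out <- purrr::map(seq_along(cameras), function(ci) {
    cam <- cameras[[ci]]
    Xc <- P %*% t(cam$R) + matrix(rep(cam$t, each = nrow(P)), ncol = 3)
    behind <- which(Xc[, 3] <= 0)
    if (length(behind) > 0) {
      b <- behind[1]
      abort(sprintf(
        "project_landmarks: point behind camera %d (frame t = %g s, landmark %s/%s)",
        ci, track$time_s[b], track$side[b], track$landmark[b]
      ), class = "fanflow_projection_error")
    }
    uv <- Xc %*% t(cam$K)
    tibble::tibble(
      camera = ci,
      time_s = track$time_s, side = track$side, landmark = track$landmark,
      u_px = uv[, 1] / uv[, 3], v_px = uv[, 2] / uv[, 3]
    )
  })
  dplyr::bind_rows(out)
}

# 3x4 projection matrix of a camera
camera_P <- function(cam) cam$K %*% cbind(cam$R, cam$t)

#' Triangulate 2D image tracks back to 3D
#'
#' Linear (DLT) least-squares triangulation of per-camera image tracks,
#' the inverse of [project_landmarks()] for exact cameras.
#'
#' @param image_tracks Tibble from [project_landmarks()] (columns `camera`,
#'   `time_s`, `side`, `landmark`, `u_px`, `v_px`).
#' @param cameras The camera list used for projection (or a perturbed rig,
#'   to study calibration-error propagation).
#' @return A `landmark_track`-shaped tibble with reconstructed `x_m`, `y_m`,
#'   `z_m`.
#' @export
triangulate_landmarks <- function(image_tracks, cameras) {
  if (length(cameras) < 2) {
    abort("triangulate_landmarks: at least 2 cameras are required",
          class = "fanflow_config_error")
  }
  Ps <- lapply(cameras, camera_P)
  keys <- dplyr::distinct(image_tracks, .data$time_s, .data$side,
                          .data$landmark)
  # index rows by observation key for fast lookup
  obs <- split(
    seq_len(nrow(image_tracks)),
    paste(image_tracks$time_s, image_tracks$side, image_tracks$landmark,
          sep = "\r")
  )
  xyz <- matrix(NA_real_, nrow(keys), 3)
  key_str <- paste(keys$time_s, keys$side, keys$landmark, sep = "\r")
  for (i in seq_len(nrow(keys))) {
    rows <- obs[[key_str[i]]]
    A <- matrix(0, 2 * length(rows), 4)
    for (j in seq_along(rows)) {
      r <- rows[j]
      P <- Ps[[image_tracks$camera[r]]]
      u <- image_tracks$u_px[r]
      v <- image_tracks$v_px[r]
      A[2 * j - 1, ] <- u * P[3, ] - P[1, ]
      A[2 * j, ] <- v * P[3, ] - P[2, ]
    }
    sv <- svd(A)
    X <- sv$v[, 4]
    xyz[i, ] <- X[1:3] / X[4]
  }
  out <- tibble::tibble(
    time_s = keys$time_s, side = keys$side, landmark = keys$landmark,
    x_m = xyz[, 1], y_m = xyz[, 2], z_m = xyz[, 3]
  )
  class(out) <- c("landmark_track", class(out))
  out
}

#' Reconstruction error of a calibration pair
#'
#' Relative error (in percent) between the known and the reconstructed
#' separation of two calibration points, the standard check of a stereo
#' calibration (the study's floor-grid diagonal: known 52.0 mm,
#' reconstructed 51.9 mm, hence ~0.2%).
#'
#' @param known_m Known separation, metres.
#' @param reconstructed_m Reconstructed separation, metres.
#' @return Relative error in percent.
#' @export
calibration_error_pct <- function(known_m, reconstructed_m) {
  if (known_m <= 0) {
    abort("calibration_error_pct: known_m must be > 0",
          class = "fanflow_config_error")
  }
  100 * abs(known_m - reconstructed_m) / known_m
}
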