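# rotate points about the horizontal axis through `pivot` directed toward
# the back of the body (-x); gamma > 0 moves a dorsal left wing away from
# the sagittal plane
rotate_about_back_axis <- function(points, pivot, gamma) {
  ry <- points[, 2] - pivot[2]
  rz <- points[, 3] - pivot[3]
  # axis -x: rotation by gamma maps y -> y cos(g) + z sin(g), z -> -y sin(g) + z cos(g)
  cbind(points[, 1],
        pivot[2] + ry * cos(gamma) + rz * sin(gamma),
        pivot[3] - ry * sin(gamma) + rz * cos(gamma))
}

#' Pose the wing surface from averaged kinematics
#'
#' Places the wingtip and the leading/trailing-edge points of the spanwise
#' sections for every requested cycle phase, using the averaged angle series
#' (and the feathering series when available, else a flat 90-degree
#' feathering). Any sagittal deconfliction rotation stored on the object is
#' applied.
#'
#' @param kin A `wing_kinematics` object (left wing).
#' @param t_hat Cycle phases to pose (default: the averaged-cycle grid).
#' @param stations Spanwise stations (fractions of R) for the sections.
#' @return Tibble: `t_hat`, `point` (`tip`/`le`/`te`), `station`, `x_m`,
#'   `y_m`, `z_m`.
#' @export
pose_wing <- function(kin, t_hat = NULL, stations = c(0.15, 0.35, 0.55, 0.75, 0.95)) {
  if (is.null(t_hat)) t_hat <- kin$cycle$t_hat
  beta <- deg2rad(kin$stroke_plane_deg)
  R <- kin$wing_length_m
  pivot <- kin$pivot_m
  mean_chord <- 0.5 * R
  interp <- function(y) {
    stats::spline(c(kin$cycle$t_hat, 1), c(y, y[1]), xout = t_hat)$y
  }
  phi <- deg2rad(interp(kin$cycle$phi_deg))
  theta <- deg2rad(interp(kin$cycle$theta_deg))
  alpha_at <- function(st, i) {
    if (is.null(kin$alpha)) return(pi / 2)
    sub <- kin$alpha[abs(kin$alpha$station -
                           kin$alpha$station[which.min(abs(kin$alpha$station - st))]) < 1e-9, ]
    deg2rad(stats::spline(c(sub$t_hat, 1), c(sub$alpha_deg, sub$alpha_deg[1]),
                          xout = t_hat[i])$y)
  }
  rows <- list()
  gamma <- deg2rad(kin$deconflict_rotation_deg)
  for (i in seq_along(t_hat)) {
    fr <- wing_frame(beta, 1, phi[i], theta[i])
    pts <- matrix(pivot + R * fr$e_r, ncol = 3)
    labs <- tibble::tibble(point = "tip", station = 1)
    for (st in stations) {
      sec <- wing_section_points(pivot, beta, 1, phi[i], theta[i],
                                 alpha_at(st, i), st, R,
                                 chord_at(st, mean_chord))
      pts <- rbind(pts, sec$le, sec$te)
      labs <- dplyr::bind_rows(labs,
                               tibble::tibble(point = c("le", "te"),
                                              station = st))
    }
    if (gamma != 0) pts <- rotate_about_back_axis(pts, pivot, gamma)
    rows[[i]] <- tibble::tibble(
      t_hat = t_hat[i], point = labs$point, station = labs$station,
      x_m = pts[, 1], y_m = pts[, 2], z_m = pts[, 3]
    )
  }
  dplyr::bind_rows(rows)
}

#' Rotate wing motion clear of the sagittal plane
#'
#' When the averaged wing motion interferes with the sagittal (symmetry)
#' plane, the whole motion is rotated by the smallest angle about the
#' horizontal axis through the wing root directed toward the back of the
#' body, until every posed wing point keeps at least `clearance_m` from the
#' plane at every phase. The rotation is a time-constant rigid rotation, so
#' wing speed is unchanged. Typical mis-registered recordings need a few
#' degrees; anything above 15 degrees is rejected as mis-registered input.
#'
#' @param kin A cycle-averaged `wing_kinematics` (left wing, sagittal plane
#'   at y = 0).
#' @param clearance_m Required clearance from the sagittal plane, metres.
#' @param resolution_deg Scan resolution for the rotation angle.
#' @return `kin` with `deconflict_rotation_deg` set (0 if already clear).
#' @export
deconflict_sagittal <- function(kin, clearance_m = 0, resolution_deg = 0.01) {
  if (clearance_m < 0) {
    abort("deconflict_sagittal: clearance_m must be >= 0",
          class = "fanflow_config_error")
  }
  t_hat <- seq(0, 1, length.out = 51)[1:50]
  posed <- pose_wing(kin, t_hat = t_hat)
  pts <- as.matrix(posed[, c("x_m", "y_m", "z_m")])
  pivot <- kin$pivot_m
  ry <- pts[, 2] - pivot[2]
  rz <- pts[, 3] - pivot[3]
  min_y_at <- function(gamma_deg) {
    g <- deg2rad(gamma_deg)
    pivot[2] + min(ry * cos(g) + rz * sin(g))
  }
  if (min_y_at(0) >= clearance_m) return(kin)
  gammas <- seq(resolution_deg, 15, by = resolution_deg)
  ok <- vapply(gammas, function(g) min_y_at(g) >= clearance_m, logical(1))
  if (!any(ok)) {
    abort(paste0("deconflict_sagittal: no rotation up to 15 degrees clears ",
                 "the sagittal plane; the input is likely mis-registered"),
          class = "fanflow_data_error")
  }
  # cumulative: the stored rotation already entered the posed points
  kin$deconflict_rotation_deg <- kin$deconflict_rotation_deg +
    gammas[which(ok)[1]]
  kin
}
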