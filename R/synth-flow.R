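#' Sample an analytic flow onto a gridded periodic field
#'
#' Evaluates an [analytic_flow_spec()] on its structured grid at
#' `snapshots_per_cycle` uniformly spaced times over one period. Steady kinds
#' (uniform, point sink, Rankine vortex) produce identical snapshots; pulsed
#' kinds are exactly periodic by construction.
#'
#' @param spec An [analytic_flow_spec()].
#' @return A [flow_field()].
#' @export
generate_flow <- function(spec) {
  ax <- lapply(1:3, function(i) {
    seq(spec$box_min_m[i], spec$box_max_m[i], by = spec$spacing_m)
  })
  dims <- c(vapply(ax, length, 1L), spec$snapshots_per_cycle)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  S <- spec$snapshots_per_cycle
  u <- array(0, dims); v <- array(0, dims); w <- array(0, dims)
  n_nodes <- nrow(pts)
  if (spec$steady) {
    uvw <- spec$evaluate(pts, 0)
    for (k in seq_len(S)) {
      u[, , , k] <- array(uvw[, 1], dims[1:3])
      v[, , , k] <- array(uvw[, 2], dims[1:3])
      w[, , , k] <- array(uvw[, 3], dims[1:3])
    }
  } else {
    for (k in seq_len(S)) {
      uvw <- spec$evaluate(pts, (k - 1) * spec$period_s / S)
      u[, , , k] <- array(uvw[, 1], dims[1:3])
      v[, , , k] <- array(uvw[, 2], dims[1:3])
      w[, , , k] <- array(uvw[, 3], dims[1:3])
    }
  }
  flow_field(u, v, w, origin_m = spec$box_min_m, spacing_m = spec$spacing_m,
             period_s = spec$period_s)
}

#' Numerical divergence of an analytic flow
#'
#' Checks the solenoidal construction of an analytic kind by evaluating
#' du/dx + dv/dy + dw/dz with 4th-order (5-point) central differences of the
#' analytic evaluator at the given points. The default step is small enough
#' that truncation and round-off together stay well below 1e-8 1/s for the
#' divergence-free kinds away from their singular points.
#'
#' @param spec An [analytic_flow_spec()].
#' @param points n x 3 matrix of evaluation points, metres.
#' @param time Evaluation time, seconds.
#' @param h Finite-difference step, metres.
#' @return Numeric vector of divergence values, 1/s.
#' @export
field_divergence <- function(spec, points, time = 0,
                             h = spec$spacing_m / 50) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  div <- numeric(nrow(points))
  for (axis in 1:3) {
    d <- rep(0, 3); d[axis] <- 1
    shift <- function(k) sweep(points, 2, -k * h * d)
    comp <- function(p) spec$evaluate(p, time)[, axis]
    # 4th-order: (-f(2h) + 8 f(h) - 8 f(-h) + f(-2h)) / (12 h)
    div <- div + (-comp(shift(2)) + 8 * comp(shift(1)) -
                    8 * comp(shift(-1)) + comp(shift(-2))) / (12 * h)
  }
  div
}

#' Simplified flapping-induced flow field
#'
#' Builds a time-periodic gridded field representing the intake stream that
#' wing fanning drives through the stroke plane: an axisymmetric stream tube
#' along the stroke-plane normal (the anterior axis when the stroke plane is
#' near-vertical), with instantaneous speed proportional to the wingtip
#' speed, a Gaussian radial profile and algebraic axial decay. Air on the
#' anterior side moves toward the moth, which is what lets backward-traced
#' particles originate in front of the head. This is a demonstration flow
#' with the correct scales and symmetries, not a surrogate for the
#' Navier-Stokes solution.
#'
#' The field scales linearly with the wingtip speed scale 2 Phi f R:
#' doubling the wingbeat frequency doubles the cycle-mean speed at any
#' probe, and zero angular velocity gives a zero field.
#'
#' @param kin A cycle-averaged `wing_kinematics` object.
#' @param spec An [analytic_flow_spec()] supplying the grid box, spacing and
#'   snapshot count (its `kind` is ignored).
#' @param entrainment Ratio of centreline intake speed to instantaneous
#'   wingtip speed.
#' @param sigma_frac Gaussian radial scale as a fraction of wing length.
#' @return A [flow_field()].
#' @export
generate_induced_flow <- function(kin, spec, entrainment = 0.25,
                                  sigma_frac = 0.75) {
  if (!inherits(kin, "wing_kinematics")) {
    abort(paste0("generate_induced_flow: kin must be a cycle-averaged ",
                 "wing_kinematics object; run reconstruct_kinematics() / ",
                 "average_cycles() first"),
          class = "fanflow_config_error")
  }
  period <- 1 / kin$frequency_hz
  R <- kin$wing_length_m
  beta <- deg2rad(kin$stroke_plane_deg)
  nrm <- stroke_frame(beta)$n

  # instantaneous wingtip speed on the cycle grid, resampled to snapshots
  tip_speed_t <- R * sqrt(kin$cycle$phi_dot_rad_s^2 *
                            cos(deg2rad(kin$cycle$theta_deg))^2 +
                            kin$cycle$theta_dot_rad_s^2)
  S <- spec$snapshots_per_cycle
  t_hat_snap <- (seq_len(S) - 1) / S
  grid <- c(kin$cycle$t_hat, 1)
  vals <- c(tip_speed_t, tip_speed_t[1])
  amp <- entrainment * stats::approx(grid, vals, xout = t_hat_snap)$y

  ax <- lapply(1:3, function(i) {
    seq(spec$box_min_m[i], spec$box_max_m[i], by = spec$spacing_m)
  })
  dims <- c(vapply(ax, length, 1L), S)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  rel <- sweep(pts, 2, kin$pivot_m * c(1, 0, 1))  # tube axis on the sagittal plane
  axial <- as.vector(rel %*% nrm)
  radial <- sqrt(pmax(rowSums(rel^2) - axial^2, 0))
  sigma <- sigma_frac * R
  # strongest under the wingtip ring (where wing speed peaks), decaying
  # along the tube axis
  profile <- exp(-(radial - 0.8 * R)^2 / (2 * sigma^2)) /
    (1 + (axial / (2 * R))^2)

  u <- array(0, dims); v <- array(0, dims); w <- array(0, dims)
  for (k in seq_len(S)) {
    speed <- -amp[k] * profile  # toward the moth on the anterior side
    u[, , , k] <- array(speed * nrm[1], dims[1:3])
    v[, , , k] <- array(speed * nrm[2], dims[1:3])
    w[, , , k] <- array(speed * nrm[3], dims[1:3])
  }
  flow_field(u, v, w, origin_m = spec$box_min_m, spacing_m = spec$spacing_m,
             period_s = period)
}
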