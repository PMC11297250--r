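# Shared fixtures, all built in code.

# a stereo rig with a wide baseline looking at the working volume
two_cameras <- function() {
  list(
    camera_model(position_m = c(0.5, 0.05, 0.1), look_at_m = c(0, 0, 0.02)),
    camera_model(position_m = c(0.1, 0.5, 0.15), look_at_m = c(0, 0, 0.02))
  )
}

# short noise-free track at the mean fanning parameters
default_track <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_landmarks(kinematics_spec())
    cache
  }
})

default_kin <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reconstruct_kinematics(default_track())
    cache
  }
})

# steady uniform field on a small box
uniform_field <- function(speed = c(0.3, 0, 0), half = 0.02,
                          spacing = 0.005, f_hz = 48.9, S = 8) {
  generate_flow(analytic_flow_spec(
    "uniform", speed_m_s = speed, frequency_hz = f_hz,
    box_min_m = rep(-half, 3), box_max_m = rep(half, 3),
    spacing_m = spacing, snapshots_per_cycle = S
  ))
}

# solid-body-rotation region of a Rankine vortex (trilinear-exact flow):
# angular velocity omega_rad_s about the z axis through the origin
solid_rotation_field <- function(omega_rad_s = pi, half = 0.04,
                                 spacing = 0.004, period_s = 1) {
  core <- 0.9 * half * sqrt(3)  # core covers the whole box
  generate_flow(analytic_flow_spec(
    "rankine_vortex", strength = omega_rad_s * 2 * pi * core^2,
    core_radius_m = core, frequency_hz = 1 / period_s,
    box_min_m = rep(-half, 3), box_max_m = rep(half, 3),
    spacing_m = spacing, snapshots_per_cycle = 4
  ))
}

# build a flow_field directly from a function u(t) at every node
node_series_field <- function(fun, S = 12, period_s = 1, n = 3,
                              spacing = 0.01) {
  u <- array(0, c(n, n, n, S)); v <- u; w <- u
  for (k in seq_len(S)) u[, , , k] <- fun((k - 1) * period_s / S)
  flow_field(u, v, w, origin_m = rep(0, 3), spacing_m = spacing,
             period_s = period_s)
}
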