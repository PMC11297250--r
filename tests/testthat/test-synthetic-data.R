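test_that("noise-free landmarks realise the prescribed stroke exactly", {
  # frame rate a whole even multiple of f, so both stroke extrema fall
  # exactly on frame times and the sampled excursion is exact
  spec <- kinematics_spec(amplitude_deg = 98, frequency_hz = 50)
  track <- generate_landmarks(spec)
  tips <- track[track$landmark == "wing_tip" & track$side == "L", ]
  pivot <- spec$pivot_m
  pe <- positional_elevation(as.matrix(tips[, c("x_m", "y_m", "z_m")]),
                             pivot, beta = pi / 180 * 99.5, side = 1)
  # continuous-time extrema of the generating sinusoid are hit at frame times
  # t = 0 and t = T/2, so the sampled excursion equals the amplitude exactly
  expect_equal(max(pe$phi * 180 / pi) - min(pe$phi * 180 / pi), 98,
               tolerance = 1e-9)

  # zero elevation: every wingtip sample lies exactly in the stroke plane
  flat <- generate_landmarks(kinematics_spec(mean_elevation_deg = 0,
                                             elevation_amplitude_deg = 0))
  tips_f <- flat[flat$landmark == "wing_tip" & flat$side == "L", ]
  pe_f <- positional_elevation(as.matrix(tips_f[, c("x_m", "y_m", "z_m")]),
                               spec$pivot_m, pi / 180 * 99.5, 1)
  expect_lt(max(abs(pe_f$theta)), 1e-12)
})

test_that("seeded noisy generation is bit-reproducible", {
  spec <- kinematics_spec(n_cycles = 1, frame_rate_hz = 1000)
  a <- generate_landmarks(spec, noise_sd = 1e-4, seed = 42)
  b <- generate_landmarks(spec, noise_sd = 1e-4, seed = 42)
  expect_identical(a$x_m, b$x_m)
  expect_identical(a$z_m, b$z_m)
  c <- generate_landmarks(spec, noise_sd = 1e-4, seed = 43)
  expect_false(identical(a$x_m, c$x_m))
})

test_that("invalid kinematics specs are rejected naming the invariant", {
  expect_error(kinematics_spec(wing_length_m = -1), "wing_length_m",
               class = "fanflow_config_error")
  expect_error(kinematics_spec(frame_rate_hz = 100), "frame_rate_hz",
               class = "fanflow_config_error")
  expect_error(kinematics_spec(amplitude_deg = 200), "amplitude_deg",
               class = "fanflow_config_error")
  expect_error(generate_landmarks(kinematics_spec(), noise_sd = -1),
               class = "fanflow_config_error")
})

test_that("projection/triangulation are an exact inverse pair", {
  track <- generate_landmarks(kinematics_spec(n_cycles = 1,
                                              frame_rate_hz = 1000))
  track <- track[track$time_s < 0.005, ]
  cams <- two_cameras()
  img <- project_landmarks(track, cams)
  rec <- triangulate_landmarks(img, cams)
  rec <- dplyr::arrange(rec, time_s, side, landmark)
  ref <- dplyr::arrange(track, time_s, side, landmark)
  err <- sqrt((rec$x_m - ref$x_m)^2 + (rec$y_m - ref$y_m)^2 +
                (rec$z_m - ref$z_m)^2)
  expect_lt(max(err), 1e-9)
})

test_that("a calibration pair separation survives the stereo round trip", {
  # two floor points a grid-diagonal apart
  pts <- tibble::tibble(
    time_s = 0, side = "C", landmark = c("grid_a", "grid_b"),
    x_m = c(0, 0.052 / sqrt(2)), y_m = c(0, 0.052 / sqrt(2)), z_m = 0
  )
  cams <- two_cameras()
  rec <- triangulate_landmarks(project_landmarks(pts, cams), cams)
  sep <- sqrt(sum((as.numeric(rec[1, c("x_m", "y_m", "z_m")]) -
                     as.numeric(rec[2, c("x_m", "y_m", "z_m")]))^2))
  expect_equal(sep, 0.052, tolerance = 1e-9)
  expect_equal(round(calibration_error_pct(0.052, 0.0519), 1), 0.2)
})

test_that("a perturbed rig propagates calibration error as an independent refit predicts", {
  pts <- tibble::tibble(
    time_s = 0, side = "C", landmark = c("p1", "p2"),
    x_m = c(-0.01, 0.02), y_m = c(0.005, -0.01), z_m = c(0.0, 0.01)
  )
  cams <- two_cameras()
  img <- project_landmarks(pts, cams)
  bad <- cams
  bad[[2]] <- camera_model(position_m = c(0.1, 0.5, 0.15) + c(5e-4, 0, 0),
                           look_at_m = c(0, 0, 0.02))
  rec <- triangulate_landmarks(img, bad)

  # independent oracle: per-point nonlinear reprojection-error minimisation
  refit <- function(u1, v1, u2, v2) {
    obj <- function(X) {
      s <- 0
      for (ci in 1:2) {
        P <- fanflow:::camera_P(bad[[ci]])
        uvw <- as.vector(P %*% c(X, 1))
        uv <- uvw[1:2] / uvw[3]
        o <- if (ci == 1) c(u1, v1) else c(u2, v2)
        s <- s + sum((uv - o)^2)
      }
      s
    }
    optim(c(0, 0, 0), obj, method = "BFGS",
          control = list(reltol = 1e-15, maxit = 500))$par
  }
  for (lm in c("p1", "p2")) {
    o <- img[img$landmark == lm, ]
    X <- refit(o$u_px[o$camera == 1], o$v_px[o$camera == 1],
               o$u_px[o$camera == 2], o$v_px[o$camera == 2])
    r <- rec[rec$landmark == lm, ]
    # DLT (algebraic) and reprojection (geometric) solutions agree to well
    # under the perturbation-induced shift itself
    expect_lt(sqrt(sum((as.numeric(r[, c("x_m", "y_m", "z_m")]) - X)^2)),
              1e-5)
  }
  # and the perturbation does move the reconstruction away from truth
  expect_gt(max(abs(rec$x_m - pts$x_m)), 1e-6)
})

test_that("point behind a camera is reported with frame and landmark", {
  pts <- tibble::tibble(time_s = 0.25, side = "L", landmark = "wing_tip",
                        x_m = 2, y_m = 0, z_m = 0)  # beyond camera 1
  expect_error(project_landmarks(pts, two_cameras()),
               "wing_tip", class = "fanflow_projection_error")
})

test_that("uniform analytic flow samples to an exactly constant field", {
  f <- uniform_field(speed = c(0.3, 0, 0))
  expect_true(all(f$u == 0.3))
  expect_true(all(f$v == 0) && all(f$w == 0))
  expect_equal(f$n_snapshots, 8)
})

test_that("point-sink nodes follow the closed-form radial speed", {
  Q <- 2e-6
  spec <- analytic_flow_spec("point_sink", strength = Q,
                             center_m = c(0, 0, 0),
                             box_min_m = rep(-0.02, 3),
                             box_max_m = rep(0.02, 3), spacing_m = 0.01,
                             snapshots_per_cycle = 4)
  f <- generate_flow(spec)
  # oracle: |u|(d) = Q / (4 pi d^2), flow directed inward
  x <- c(0.02, 0.01, 0.01)
  d <- sqrt(sum(x^2))
  uvw <- spec$evaluate(matrix(x, 1), 0)
  expect_equal(sqrt(sum(uvw^2)), Q / (4 * pi * d^2), tolerance = 1e-12)
  expect_lt(sum(uvw * x), 0)
  # grid snapshot holds the same nodal values and the field is steady
  expect_equal(f$u[5, 3, 3, 1],
               spec$evaluate(matrix(c(0.02, 0, 0), 1), 0)[1, 1],
               tolerance = 1e-12)
  expect_identical(f$u[, , , 1], f$u[, , , 4])
})

test_that("divergence-free kinds are numerically solenoidal", {
  pts <- rbind(c(0.012, 0.006, 0.004), c(-0.008, 0.01, -0.006),
               c(0.015, -0.012, 0.008))
  sink <- analytic_flow_spec("point_sink", strength = 1e-6,
                             spacing_m = 0.005)
  expect_lt(max(abs(field_divergence(sink, pts))), 1e-8)
  vort <- analytic_flow_spec("rankine_vortex", strength = 1e-4,
                             core_radius_m = 0.02, spacing_m = 0.005)
  # interior of the solid-body core and the irrotational exterior
  # (the core boundary itself is only C0, so points straddle neither side)
  inner <- rbind(c(0.004, 0.003, 0.0), c(-0.005, 0.002, 0.01))
  outer <- rbind(c(0.03, 0.02, 0.0), c(-0.028, -0.025, 0.01))
  expect_lt(max(abs(field_divergence(vort, inner))), 1e-8)
  expect_lt(max(abs(field_divergence(vort, outer))), 1e-8)
  dip <- analytic_flow_spec("flapping_dipole", strength = 1e-7,
                            spacing_m = 0.005)
  expect_lt(max(abs(field_divergence(dip, pts, time = 0.3 / 48.9, h = 2e-5))), 1e-8)
})

test_that("pulsed kinds are exactly periodic snapshot stacks", {
  spec <- analytic_flow_spec("pulsed_jet", speed_m_s = 0.5,
                             snapshots_per_cycle = 10)
  p <- matrix(c(0.01, 0.002, 0.001), 1)
  expect_equal(spec$evaluate(p, 0.2 * spec$period_s),
               spec$evaluate(p, 1.2 * spec$period_s), tolerance = 1e-12)
  f <- generate_flow(spec)
  expect_equal(f$n_snapshots, 10)
})

test_that("induced flow vanishes without motion and scales linearly with f", {
  kin <- default_kin()
  grid <- analytic_flow_spec("uniform", frequency_hz = kin$frequency_hz,
                             box_min_m = c(-0.05, -0.05, -0.03),
                             box_max_m = c(0.08, 0.05, 0.07),
                             spacing_m = 0.006, snapshots_per_cycle = 20)
  still <- kin
  still$cycle$phi_dot_rad_s <- 0
  still$cycle$theta_dot_rad_s <- 0
  f0 <- generate_induced_flow(still, grid)
  expect_true(all(f0$u == 0) && all(f0$w == 0))

  f1 <- generate_induced_flow(kin, grid)
  fast <- kin
  fast$frequency_hz <- 2 * kin$frequency_hz
  fast$cycle$phi_dot_rad_s <- 2 * kin$cycle$phi_dot_rad_s
  fast$cycle$theta_dot_rad_s <- 2 * kin$cycle$theta_dot_rad_s
  f2 <- generate_induced_flow(fast, grid)
  probe <- matrix(c(0.02, 0.005, 0.03), 1)
  m1 <- mean(sapply(seq(0, 1, length.out = 40)[1:39], function(th)
    sqrt(sum(velocity_at(f1, probe, th / kin$frequency_hz)^2))))
  m2 <- mean(sapply(seq(0, 1, length.out = 40)[1:39], function(th)
    sqrt(sum(velocity_at(f2, probe, th / fast$frequency_hz)^2))))
  expect_equal(m2 / m1, 2, tolerance = 1e-6)
  # and the cycle-mean speed near the antenna has the observed scale (~0.1 m/s)
  expect_gt(m1, 0.05)
  expect_lt(m1, 1)

  expect_error(generate_induced_flow(kin$cycle, grid), "average",
               class = "fanflow_config_error")
})
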