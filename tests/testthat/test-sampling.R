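test_that("particles in a zero field stay at their stations", {
  f <- uniform_field(speed = c(0, 0, 0))
  ant <- virtual_antenna(base_m = c(0, 0, 0), tip_m = c(0.01, 0.005, 0.005),
                         n_stations = 4)
  tr <- backtrace(f, ant, trace_config(n_release_phases = 3,
                                       steps_per_cycle = 50, n_cycles = 2))
  expect_equal(nrow(tr$origins), 4 * 3 * 2)
  start <- ant$stations[tr$origins$station, ]
  expect_equal(as.matrix(tr$origins[, c("x_m", "y_m", "z_m")]), start,
               tolerance = 1e-15, ignore_attr = TRUE)
  fc <- forward_check(f, tr)
  expect_equal(max(fc$roundtrip_error_m), 0)
})

test_that("uniform-flow origins follow the closed-form displacement", {
  f_hz <- 48.9
  U <- c(0.3, 0, 0)
  f <- uniform_field(speed = U, half = 0.02, f_hz = f_hz)
  ant <- virtual_antenna(base_m = c(0.01, 0, 0), tip_m = c(0.012, 0.005, 0.005),
                         n_stations = 3)
  tr <- backtrace(f, ant, trace_config(n_release_phases = 2,
                                       steps_per_cycle = 500, n_cycles = 1))
  # Euler in a constant field is exact: origin = station - U * T
  o1 <- tr$origins[tr$origins$cycles_back == 1, ]
  expected <- ant$stations[o1$station, ] -
    matrix(rep(U / f_hz, each = nrow(o1)), ncol = 3)
  expect_equal(as.matrix(o1[, c("x_m", "y_m", "z_m")]), expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  # displacement magnitude: |U| T = 6.13 mm per wingbeat
  d <- sqrt(rowSums((as.matrix(o1[, c("x_m", "y_m", "z_m")]) -
                       ant$stations[o1$station, ])^2))
  expect_equal(d, rep(0.3 / 48.9, nrow(o1)), tolerance = 1e-12)
  # constant-field round trip is exact
  expect_lt(max(forward_check(f, tr)$roundtrip_error_m), 1e-12)
})

test_that("point-sink backtracing follows the radial cube law", {
  Q <- 1e-5
  f_hz <- 48.9
  f <- generate_flow(analytic_flow_spec(
    "point_sink", strength = Q, center_m = c(0, 0, 0), frequency_hz = f_hz,
    box_min_m = rep(-0.02, 3), box_max_m = rep(0.02, 3),
    spacing_m = 0.001, snapshots_per_cycle = 4
  ))
  r0 <- 0.01
  start <- matrix(c(r0, 0, 0), 1)
  n_cycles <- 5
  tr <- backtrace(f, start, trace_config(n_release_phases = 1,
                                         steps_per_cycle = 500,
                                         n_cycles = n_cycles,
                                         integrator = "rk4"))
  o <- tr$origins[tr$origins$cycles_back == n_cycles, ]
  r_end <- sqrt(o$x_m^2 + o$y_m^2 + o$z_m^2)
  t_total <- n_cycles / f_hz
  expected_r3 <- r0^3 + 3 * Q * t_total / (4 * pi)
  expect_equal((r_end^3 - r0^3) / (expected_r3 - r0^3), 1, tolerance = 0.05)
})

test_that("tracing is deterministic and steady fields collapse release phases", {
  f <- solid_rotation_field(omega_rad_s = 2, half = 0.03, spacing = 0.005)
  ant <- virtual_antenna(base_m = c(0.01, 0, 0), tip_m = c(0.015, 0.005, 0),
                         n_stations = 3)
  cfg <- trace_config(n_release_phases = 4, steps_per_cycle = 100,
                      n_cycles = 2)
  a <- backtrace(f, ant, cfg)
  b <- backtrace(f, ant, cfg)
  expect_identical(a$origins, b$origins)
  # steady field: origins are independent of the release phase
  o <- a$origins[a$origins$cycles_back == 2, ]
  for (st in 1:3) {
    xs <- o$x_m[o$station == st]
    expect_lt(diff(range(xs)), 1e-12)
  }
})

test_that("rk4 round trip on a smooth vortex stays below 1e-3 of path length", {
  f <- solid_rotation_field(omega_rad_s = pi, half = 0.04, spacing = 0.004,
                            period_s = 1 / 48.9)
  ant <- virtual_antenna(base_m = c(0.01, 0, 0.002),
                         tip_m = c(0.015, 0.008, 0.006), n_stations = 21)
  cfg <- trace_config(n_release_phases = 21, steps_per_cycle = 500,
                      n_cycles = 5, integrator = "rk4")
  tr <- backtrace(f, ant, cfg)
  expect_equal(nrow(tr$release_points) * cfg$n_release_phases, 441)
  fc <- forward_check(f, tr)
  # path length ~ omega * t_total * r
  t_total <- 5 / 48.9
  path_len <- pi * t_total * 0.012
  expect_lt(max(fc$roundtrip_error_m), 1e-3 * path_len)
})

test_that("integrator order: Euler is first order, rk4 fourth order", {
  omega <- pi
  f <- solid_rotation_field(omega_rad_s = omega, half = 0.04,
                            spacing = 0.004, period_s = 1)
  start <- matrix(c(0.01, 0, 0), 1)
  # solid-body rotation: tracing back one period rotates by -omega*T
  exact <- c(0.01 * cos(-omega), 0.01 * sin(-omega), 0)
  origin_err <- function(n, integ) {
    tr <- backtrace(f, start, trace_config(n_release_phases = 1,
                                           steps_per_cycle = n, n_cycles = 1,
                                           integrator = integ))
    o <- tr$origins[tr$origins$cycles_back == 1, ]
    sqrt(sum((c(o$x_m, o$y_m, o$z_m) - exact)^2))
  }
  e1 <- origin_err(100, "euler"); e2 <- origin_err(200, "euler")
  order_euler <- log2(e1 / e2)
  expect_lt(abs(order_euler - 1), 0.2)
  r1 <- origin_err(50, "rk4"); r2 <- origin_err(100, "rk4")
  order_rk4 <- log2(r1 / r2)
  expect_lt(abs(order_rk4 - 4), 0.8)
})

test_that("trajectories leaving the box are truncated, flagged and excluded", {
  f <- uniform_field(speed = c(0.5, 0, 0), half = 0.02, f_hz = 48.9)
  # backward motion is -x; a station near the -x face exits quickly
  start <- rbind(c(-0.015, 0, 0), c(0.015, 0, 0))
  tr <- backtrace(f, start, trace_config(n_release_phases = 1,
                                         steps_per_cycle = 100, n_cycles = 2))
  o <- tr$origins[tr$origins$cycles_back == 2, ]
  expect_true(o$truncated[o$station == 1])
  expect_false(o$truncated[o$station == 2])
  expect_equal(tr$n_truncated, 1)
  vol <- assemble_sampling_volume(tr, head_m = c(0, 0, 0))
  hr <- head_relative_coordinates(vol)
  expect_equal(nrow(hr), sum(!vol$origins$truncated))
})

test_that("sampling volumes collapse to the stations for a stationary trace", {
  f <- uniform_field(speed = c(0, 0, 0))
  ant <- virtual_antenna(base_m = c(0.012, 0.004, 0.016),
                         tip_m = c(0.018, 0.008, 0.02), n_stations = 5)
  tr <- backtrace(f, ant, trace_config(n_release_phases = 1,
                                       steps_per_cycle = 10, n_cycles = 1))
  head <- c(0.015, 0, 0.012)
  vol <- assemble_sampling_volume(tr, head_m = head)
  hr <- head_relative_coordinates(vol)
  d_expected <- sqrt(rowSums(sweep(ant$stations, 2, head)^2))
  expect_equal(hr$distance_m, d_expected, tolerance = 1e-12)

  # uniform anterior-to-posterior flow: all origins dead ahead of the head
  f2 <- uniform_field(speed = c(-0.3, 0, 0), half = 0.05, spacing = 0.01)
  ant2 <- virtual_antenna(base_m = c(0.0, 0, 0.0), tip_m = c(0.002, 0, 0),
                          n_stations = 3)
  tr2 <- backtrace(f2, ant2, trace_config(n_release_phases = 3,
                                          steps_per_cycle = 100,
                                          n_cycles = 3))
  vol2 <- assemble_sampling_volume(tr2, head_m = c(-0.01, 0, 0))
  hr2 <- head_relative_coordinates(vol2)
  expect_lt(max(abs(hr2$h_angle_deg)), 1e-9)
  expect_lt(max(abs(hr2$v_angle_deg)), 1e-9)
})
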