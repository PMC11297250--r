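test_that("body angle is the signed elevation of the head-abdomen axis", {
  expect_equal(body_angle(c(1, 0, 0), c(0, 0, 0)), 0)
  expect_equal(body_angle(c(1, 0, 1), c(0, 0, 0)), pi / 4)
  expect_equal(body_angle(c(0, 0, -1), c(0, 0, 0)), -pi / 2)
  expect_error(body_angle(c(1, 1, 1), c(1, 1, 1)),
               class = "fanflow_geometry_error")
  # generator -> recovery identity at the measured mean body angle
  kin <- default_kin()
  expect_equal(kin$body_angle_deg, -0.6, tolerance = 0.01)
})

test_that("stroke-plane fit recovers exact planes including near-vertical ones", {
  phi <- seq(0, 2 * pi, length.out = 40)
  for (beta_deg in c(99.5, 0, 90, 45)) {
    b <- beta_deg * pi / 180
    s <- c(cos(b), 0, sin(b))
    pivot <- c(0.01, 0.004, 0.012)
    tips <- t(pivot + 0.017 * (outer(s, sin(phi)) +
                                 outer(c(0, 1, 0), cos(phi))))
    expect_equal(fit_stroke_plane(tips, pivot) * 180 / pi, beta_deg,
                 tolerance = 1e-9)
    # translation invariance
    expect_equal(fit_stroke_plane(sweep(tips, 2, c(-1, 2, 0.5)), pivot),
                 fit_stroke_plane(tips, pivot), tolerance = 1e-12)
    # uniform resampling invariance (every second sample, exact path)
    expect_equal(fit_stroke_plane(tips[seq(1, 40, 2), ], pivot) * 180 / pi,
                 beta_deg, tolerance = 1e-9)
  }
})

test_that("stroke-plane fit is unbiased under tracking noise (Monte Carlo)", {
  phi <- seq(0, 2 * pi, length.out = 60)
  s <- c(cos(pi / 2), 0, sin(pi / 2))
  tips0 <- t(0.017 * (outer(s, sin(phi)) + outer(c(0, 1, 0), cos(phi))))
  set.seed(101)
  est <- replicate(100, {
    tips <- tips0 + matrix(rnorm(length(tips0), 0, 1e-4), ncol = 3)
    fit_stroke_plane(tips, c(0, 0, 0)) * 180 / pi
  })
  expect_lt(abs(mean(est) - 90), 0.5)
})

test_that("positional/elevation angles match their defining geometry", {
  b <- 99.5 * pi / 180
  s <- c(cos(b), 0, sin(b))
  piv <- c(0, 0.004, 0.012)
  # tip in the stroke plane on the horizontal through the pivot
  pe <- positional_elevation(piv + 0.017 * c(0, 1, 0), piv, b, 1)
  expect_equal(c(pe$phi, pe$theta), c(0, 0), tolerance = 1e-12)
  # tip in the stroke plane "straight up" along the inclined direction
  pe <- positional_elevation(piv + 0.017 * s, piv, b, 1)
  expect_equal(c(pe$phi, pe$theta), c(pi / 2, 0), tolerance = 1e-12)
  # normal to the stroke plane: degenerate, flagged
  n <- c(sin(b), 0, -cos(b))
  pe <- positional_elevation(piv + 0.01 * n, piv, b, 1)
  expect_true(pe$degenerate)
  expect_true(is.na(pe$phi))
  expect_equal(pe$theta, pi / 2, tolerance = 1e-12)
  expect_error(positional_elevation(piv, piv, b, 1),
               class = "fanflow_geometry_error")
  # mean-elevation recovery identity at the measured Table value
  expect_equal(default_kin()$mean_elevation_deg, -23.8, tolerance = 0.1)
})

test_that("sectional velocity components follow the blade-element formulas", {
  w90 <- wing_velocity_components(1, pi, 0, pi / 2, 0)
  expect_equal(c(w90$v_h, w90$v_v), c(0, pi), tolerance = 1e-12)
  w0 <- wing_velocity_components(1, pi, 0, 0, 0)
  expect_equal(c(w0$v_h, w0$v_v), c(-pi, 0), tolerance = 1e-12)
  w45 <- wing_velocity_components(1, 1, 0, pi / 4, 0)
  expect_equal(c(w45$v_h, w45$v_v), c(-sqrt(2) / 2, sqrt(2) / 2),
               tolerance = 1e-12)
})

test_that("speed magnitude identity and AoA range hold for random section states", {
  # the printed component pair preserves the section-frame speed
  # r * ||(phi_dot cos(theta), theta_dot)|| whenever a single rate acts or
  # the section is parallel/normal to the stroke plane
  set.seed(7)
  for (i in 1:200) {
    r <- runif(1, 0.001, 0.02)
    th <- runif(1, -pi / 3, pi / 3)
    pd <- runif(1, -500, 500)
    td <- runif(1, -200, 200)
    al <- runif(1, 0, pi)
    switch(i %% 4 + 1,
           td <- 0,            # pure positional rotation
           pd <- 0,            # pure elevation rotation
           al <- 0,            # chord in the stroke plane
           al <- pi / 2)       # chord normal to the stroke plane
    vc <- wing_velocity_components(r, pd, td, al, th)
    expect_equal(sqrt(vc$v_h^2 + vc$v_v^2),
                 r * sqrt(pd^2 * cos(th)^2 + td^2), tolerance = 1e-10)
    aoa <- angle_of_attack(vc$v_h, vc$v_v)
    if (!is.na(aoa)) expect_true(aoa >= 0 && aoa <= pi)
  }
  # and AoA stays in range for fully general states
  for (i in 1:100) {
    vc <- wing_velocity_components(runif(1, 0.001, 0.02),
                                   runif(1, -500, 500), runif(1, -200, 200),
                                   runif(1, 0, pi), runif(1, -pi / 3, pi / 3))
    aoa <- angle_of_attack(vc$v_h, vc$v_v)
    expect_true(is.na(aoa) || (aoa >= 0 && aoa <= pi))
  }
})

test_that("angle of attack follows the arccos rule, with folding", {
  expect_equal(angle_of_attack(0, 1), pi / 2)
  expect_equal(angle_of_attack(1, 0), 0)
  expect_equal(angle_of_attack(-sqrt(2) / 2, sqrt(2) / 2) * 180 / pi, 135,
               tolerance = 1e-12)
  expect_equal(angle_of_attack(-sqrt(2) / 2, sqrt(2) / 2, fold = TRUE) *
                 180 / pi, 45, tolerance = 1e-12)
  expect_true(is.na(angle_of_attack(0, 0)))
})

test_that("dimensionless numbers are exact closed forms", {
  expect_identical(schmidt_number(fluid_constants(1.5e-5, 2.5e-6)), 6)
  v <- mean_tip_speed(98, 48.9, 0.0173)
  expect_equal(v, 2 * (98 * pi / 180) * 48.9 * 0.0173)
  # doubling the amplitude doubles tip speed and Re exactly
  expect_identical(mean_tip_speed(196, 48.9, 0.0173), 2 * v)
  re <- reynolds_number(98, 48.9, 0.0173, 0.0086)
  expect_equal(re, v * 0.0086 / 1.5e-5)
  expect_identical(reynolds_number(196, 48.9, 0.0173, 0.0086), 2 * re)
  # the study regime: Re of order 10^3
  expect_gt(re, 1000); expect_lt(re, 2500)
})

test_that("cycle averaging is idempotent, symmetric and linear", {
  f <- 50  # 40 frames per cycle exactly, extrema on frame times
  t <- seq(0, 4 / f, by = 1 / 2000)
  base <- function(t) 49 * cos(2 * pi * f * t) - 23
  df <- tibble::tibble(time_s = t, phi_deg = base(t))
  avg <- average_cycles(df)
  expect_equal(avg$frequency_hz, f, tolerance = 1e-3)
  # identical cycles in: the average equals any single cycle
  expect_lt(max(abs(avg$cycle$phi_deg - base(avg$cycle$t_hat / f))), 0.05)

  # left series and its exact mirror as right: average equals both
  df2 <- dplyr::bind_rows(
    tibble::tibble(time_s = t, side = "L", phi_deg = base(t)),
    tibble::tibble(time_s = t, side = "R", phi_deg = base(t))
  )
  avg2 <- average_cycles(df2)
  expect_equal(avg2$cycle$phi_deg, avg$cycle$phi_deg, tolerance = 1e-9)

  # +delta / -delta perturbed sides average back to the unperturbed cycle
  # (a cos-2f perturbation keeps the downstroke-start peaks in place)
  pert <- 3 * cos(4 * pi * f * t)
  dfp <- dplyr::bind_rows(
    tibble::tibble(time_s = t, side = "L", phi_deg = base(t) + pert),
    tibble::tibble(time_s = t, side = "R", phi_deg = base(t) - pert)
  )
  avgp <- average_cycles(dfp)
  expect_equal(avgp$cycle$phi_deg, avg$cycle$phi_deg, tolerance = 1e-4)

  # commutes with a constant offset
  dfo <- tibble::tibble(time_s = t, phi_deg = base(t) + 10)
  expect_equal(average_cycles(dfo)$cycle$phi_deg, avg$cycle$phi_deg + 10,
               tolerance = 1e-9)

  expect_error(average_cycles(tibble::tibble(time_s = t[1:10],
                                             phi_deg = base(t[1:10]))),
               class = "fanflow_data_error")
})

test_that("noise-free reconstruction recovers the generating parameters", {
  kin <- default_kin()
  g <- glance(kin)
  expect_equal(g$frequency_hz, 48.9, tolerance = 0.005 * 48.9)
  expect_equal(g$amplitude_deg, 98, tolerance = 0.005 * 98)
  expect_lt(abs(g$stroke_plane_deg - 99.5), 0.1)
  expect_lt(abs(g$mean_elevation_deg - (-23.8)), 0.1)
  expect_lt(abs(g$body_angle_deg - (-0.6)), 0.01)
  expect_equal(g$wing_length_m, 0.0173, tolerance = 1e-6)

  # full angle-series identity, 0.1 deg RMS
  th <- kin$cycle$t_hat
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(kin$cycle$phi_deg - 49 * cos(2 * pi * th)), 0.1)
  expect_lt(rms(kin$cycle$theta_deg - (-23.8 + 5 * sin(2 * pi * th))), 0.1)
  a <- kin$alpha
  pred <- 90 + 25 * a$station * cos(2 * pi * a$t_hat + pi / 2) +
    10 * a$station * cos(4 * pi * a$t_hat)
  expect_lt(rms(a$alpha_deg - pred), 0.1)
})

test_that("angle of attack varies along the span because the twist does", {
  aoa <- angle_of_attack_series(default_kin())
  wide <- tidyr::pivot_wider(aoa[, c("t_hat", "station", "aoa_deg")],
                             names_from = "station", values_from = "aoa_deg")
  # spanwise variation at a fixed instant reaches several degrees
  expect_gt(max(abs(wide$`1` - wide$`0.2`), na.rm = TRUE), 5)
  # both the raw and the folded convention are emitted, folded within [0, 90]
  expect_true(all(aoa$aoa_folded_deg <= 90 + 1e-9, na.rm = TRUE))
  expect_true(all(aoa$aoa_deg <= 180 + 1e-9, na.rm = TRUE))
})

test_that("sagittal deconfliction is identity when clear and matches a closed-form oracle", {
  kin <- default_kin()
  out <- deconflict_sagittal(kin)
  expect_identical(out$deconflict_rotation_deg, kin$deconflict_rotation_deg)
  expect_identical(out$cycle, kin$cycle)

  # closed-form oracle: each posed point needs the smallest gamma >= 0 with
  # A cos(gamma - psi) >= clearance - pivot_y; the binding point decides
  oracle_rot <- function(k, clearance = 0) {
    posed <- pose_wing(k, t_hat = seq(0, 1, length.out = 51)[1:50])
    ry <- posed$y_m - k$pivot_m[2]
    rz <- posed$z_m - k$pivot_m[3]
    A <- sqrt(ry^2 + rz^2)
    psi <- atan2(rz, ry)
    cc <- pmin(pmax((clearance - k$pivot_m[2]) / A, -1), 1)
    a <- acos(cc)
    need <- ifelse(psi - a <= 0 & psi + a >= 0, 0, psi - a)
    max(need) * 180 / pi
  }

  # a dorsally shifted stroke in a vertical stroke plane interferes with the
  # sagittal plane near pronation (the clap), where a back-axis rotation can
  # clear it; theta = 0 and a 90-degree feathering keep every posed point at
  # y = pivot_y + r cos(phi), so the closed form is exact
  t_hat <- seq(0, 1, length.out = 200 + 1)[1:200]
  base <- structure(list(
    cycle = tibble::tibble(
      t_hat = t_hat,
      phi_deg = 75 + 20 * cos(2 * pi * t_hat),
      theta_deg = 0,
      phi_dot_rad_s = -20 * pi / 180 * 2 * pi * 48.9 * sin(2 * pi * t_hat),
      theta_dot_rad_s = 0
    ),
    alpha = NULL, stroke_plane_deg = 90, body_angle_deg = 0,
    frequency_hz = 48.9, amplitude_deg = 40, mean_elevation_deg = 0,
    wing_length_m = 0.0173, pivot_m = c(0, 0.0008, 0.012), n_cycles = 1,
    deconflict_rotation_deg = 0
  ), class = "wing_kinematics")
  expected0 <- oracle_rot(base)
  expect_gt(expected0, 0)  # the fixture does penetrate
  fixed <- deconflict_sagittal(base)
  expect_lt(abs(fixed$deconflict_rotation_deg - expected0), 0.2)

  # pre-rotating the whole motion by -delta adds exactly delta to the
  # required rotation; choose the pre-rotation for a mild 5-8 degree case
  pen <- base
  pen$deconflict_rotation_deg <- expected0 - 6.5
  expect_lt(abs(oracle_rot(pen) - 6.5), 1e-6)
  fixed2 <- deconflict_sagittal(pen)
  reported <- fixed2$deconflict_rotation_deg - pen$deconflict_rotation_deg
  expect_lt(abs(reported - 6.5), 0.2)
  expect_gt(reported, 5); expect_lt(reported, 8)

  # gross mis-registration (> 15 degrees required) is rejected
  pen$deconflict_rotation_deg <- expected0 - 20
  expect_error(deconflict_sagittal(pen), class = "fanflow_data_error")
})
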