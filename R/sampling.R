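#' Trace particles backward in time from the antenna
#'
#' Releases massless particles from every antenna station at
#' `n_release_phases` equally spaced phases of the wingbeat cycle and
#' integrates dx/dt = -u(x, t) in reversed time through the periodic flow
#' field: at each step the particle moves by velocity times time step
#' (explicit Euler, the reference advection rule; `rk4` is available for
#' convergence checks). Positions after each whole cycle backward are
#' recorded, so arrival-time-resolved statistics can be formed. All
#' trajectories are advanced together (the integration is vectorised over
#' particles), and the computation is fully deterministic.
#'
#' A particle that leaves the grid box is truncated: its position freezes at
#' the last inside point and the trajectory is flagged (`out_of_domain =
#' "freeze"` instead clamps the velocity lookup and keeps integrating).
#'
#' @param field A [flow_field()].
#' @param antenna A [virtual_antenna()], or an n x 3 matrix of custom release
#'   points.
#' @param cfg A [trace_config()].
#' @return Object of class `particle_trace`: list with `origins` (tibble:
#'   `station`, `phase`, `release_t_hat`, `cycles_back`, `x_m`, `y_m`,
#'   `z_m`, `truncated`), `paths` (tibble of every step when
#'   `cfg$record == "full"`, else `NULL`), `cfg`, and the release points.
#' @export
backtrace <- function(field, antenna, cfg = trace_config()) {
  start <- if (inherits(antenna, "virtual_antenna")) antenna$stations
           else as.matrix(antenna)
  lo <- field$origin_m
  hi <- field$box_max_m
  if (any(start[, 1] < lo[1] | start[, 1] > hi[1] |
            start[, 2] < lo[2] | start[, 2] > hi[2] |
            start[, 3] < lo[3] | start[, 3] > hi[3])) {
    abort("backtrace: release point outside the flow domain",
          class = "fanflow_domain_error")
  }
  n_st <- nrow(start)
  n_ph <- cfg$n_release_phases
  T_s <- field$period_s
  dt <- T_s / cfg$steps_per_cycle
  n_steps <- cfg$steps_per_cycle * cfg$n_cycles

  # one big particle set: station index varies fastest
  station <- rep(seq_len(n_st), times = n_ph)
  phase <- rep(seq_len(n_ph), each = n_st)
  release_t_hat <- (phase - 1) / n_ph
  X <- start[station, , drop = FALSE]
  tau <- release_t_hat * T_s
  N <- nrow(X)
  active <- rep(TRUE, N)
  truncated <- rep(FALSE, N)

  origins <- array(NA_real_, c(N, cfg$n_cycles, 3))
  paths <- if (cfg$record == "full") {
    arr <- array(NA_real_, c(N, n_steps + 1, 3))
    arr[, 1, ] <- X
    arr
  } else NULL

  inside <- function(P) {
    P[, 1] >= lo[1] & P[, 1] <= hi[1] &
      P[, 2] >= lo[2] & P[, 2] <= hi[2] &
      P[, 3] >= lo[3] & P[, 3] <= hi[3]
  }

  for (step in seq_len(n_steps)) {
    if (any(active)) {
      idx <- which(active)
      Xa <- X[idx, , drop = FALSE]
      ta <- tau[idx]
      if (cfg$integrator == "euler") {
        Xn <- Xa - dt * velocity_at(field, Xa, ta, out_of_domain = "freeze")
      } else {
        k1 <- -velocity_at(field, Xa, ta, out_of_domain = "freeze")
        k2 <- -velocity_at(field, clamp_box(Xa + dt / 2 * k1, lo, hi),
                           ta - dt / 2, out_of_domain = "freeze")
        k3 <- -velocity_at(field, clamp_box(Xa + dt / 2 * k2, lo, hi),
                           ta - dt / 2, out_of_domain = "freeze")
        k4 <- -velocity_at(field, clamp_box(Xa + dt * k3, lo, hi),
                           ta - dt, out_of_domain = "freeze")
        Xn <- Xa + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      ok <- inside(Xn)
      if (cfg$out_of_domain == "truncate") {
        if (any(!ok)) {
          left <- idx[!ok]
          truncated[left] <- TRUE
          active[left] <- FALSE
        }
        keep <- idx[ok]
        X[keep, ] <- Xn[ok, , drop = FALSE]
      } else {
        X[idx, ] <- clamp_box(Xn, lo, hi)
      }
    }
    tau <- tau - dt
    if (!is.null(paths)) paths[, step + 1, ] <- X
    if (step %% cfg$steps_per_cycle == 0) {
      origins[, step %/% cfg$steps_per_cycle, ] <- X
    }
  }

  origins_df <- tibble::tibble(
    station = rep(station, times = cfg$n_cycles),
    phase = rep(phase, times = cfg$n_cycles),
    release_t_hat = rep(release_t_hat, times = cfg$n_cycles),
    cycles_back = rep(seq_len(cfg$n_cycles), each = N),
    x_m = as.vector(origins[, , 1]),
    y_m = as.vector(origins[, , 2]),
    z_m = as.vector(origins[, , 3]),
    truncated = rep(truncated, times = cfg$n_cycles)
  )
  paths_df <- NULL
  if (!is.null(paths)) {
    paths_df <- tibble::tibble(
      station = rep(station, times = n_steps + 1),
      phase = rep(phase, times = n_steps + 1),
      step = rep(0:n_steps, each = N),
      t_s = rep(release_t_hat * T_s, times = n_steps + 1) -
        rep(0:n_steps, each = N) * dt,
      x_m = as.vector(paths[, , 1]),
      y_m = as.vector(paths[, , 2]),
      z_m = as.vector(paths[, , 3]),
      truncated = rep(truncated, times = n_steps + 1)
    )
  }
  structure(
    list(origins = origins_df, paths = paths_df, cfg = cfg,
         release_points = start, period_s = T_s,
         n_truncated = sum(truncated)),
    class = "particle_trace"
  )
}

clamp_box <- function(P, lo, hi) {
  P[, 1] <- pmin(pmax(P[, 1], lo[1]), hi[1])
  P[, 2] <- pmin(pmax(P[, 2], lo[2]), hi[2])
  P[, 3] <- pmin(pmax(P[, 3], lo[3]), hi[3])
  P
}

#' @export
print.particle_trace <- function(x, ...) {
  n_traj <- nrow(x$release_points) * x$cfg$n_release_phases
  cat("<particle_trace>\n")
  cat(sprintf("  %d trajectories (%d stations x %d phases), %d steps/cycle x %d cycles (%s)\n",
              n_traj, nrow(x$release_points), x$cfg$n_release_phases,
              x$cfg$steps_per_cycle, x$cfg$n_cycles, x$cfg$integrator))
  cat(sprintf("  truncated at the domain boundary: %d\n", x$n_truncated))
  invisible(x)
}

#' Time-reversal round-trip check of the tracer
#'
#' Re-advects the recorded final origins forward in time with the same
#' scheme, step and horizon, and returns the distance between each
#' trajectory's forward end point and its release point. Exactly zero for a
#' constant field; small (integrator-order) for smooth fields.
#'
#' @param field The [flow_field()] used for tracing.
#' @param trace A `particle_trace` from [backtrace()].
#' @return Tibble: `station`, `phase`, `roundtrip_error_m` (truncated
#'   trajectories are skipped).
#' @export
forward_check <- function(field, trace) {
  cfg <- trace$cfg
  T_s <- trace$period_s
  dt <- T_s / cfg$steps_per_cycle
  n_steps <- cfg$steps_per_cycle * cfg$n_cycles
  final <- trace$origins[trace$origins$cycles_back == cfg$n_cycles &
                           !trace$origins$truncated, ]
  if (nrow(final) == 0) {
    abort("forward_check: no untruncated trajectories",
          class = "fanflow_data_error")
  }
  X <- as.matrix(final[, c("x_m", "y_m", "z_m")])
  tau <- final$release_t_hat * T_s - n_steps * dt
  lo <- field$origin_m
  hi <- field$box_max_m
  for (step in seq_len(n_steps)) {
    if (cfg$integrator == "euler") {
      # exact inverse of the backward Euler update: x_{k} = x_{k+1} - dt u(x_k, t_k)
      # cannot be inverted in closed form, so the forward pass uses the same
      # explicit rule; the mismatch is the round-trip error being measured
      X <- X + dt * velocity_at(field, X, tau, out_of_domain = "freeze")
    } else {
      k1 <- velocity_at(field, X, tau, out_of_domain = "freeze")
      k2 <- velocity_at(field, clamp_box(X + dt / 2 * k1, lo, hi),
                        tau + dt / 2, out_of_domain = "freeze")
      k3 <- velocity_at(field, clamp_box(X + dt / 2 * k2, lo, hi),
                        tau + dt / 2, out_of_domain = "freeze")
      k4 <- velocity_at(field, clamp_box(X + dt * k3, lo, hi),
                        tau + dt, out_of_domain = "freeze")
      X <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    tau <- tau + dt
  }
  start <- trace$release_points[final$station, , drop = FALSE]
  tibble::tibble(
    station = final$station, phase = final$phase,
    roundtrip_error_m = sqrt(rowSums((X - start)^2))
  )
}

#' Assemble the sampling volume
#'
#' Collects the per-cycle origin positions of the backward trajectories,
#' tagged by their arrival-time offset (cycles to arrival), into a sampling
#' volume referenced to the head position and resting heading. Truncated
#' trajectories are retained but flagged; downstream statistics exclude them
#' by default.
#'
#' @param trace A `particle_trace` from [backtrace()].
#' @param head_m Head-tip position, metres.
#' @param heading Unit vector of the resting heading (default anterior x).
#' @param mirrored Set `TRUE` if the trace already represents both wings.
#' @return Object of class `sampling_volume`: list with `origins` tibble
#'   (`cycles_to_arrival`, `x_m`, `y_m`, `z_m`, `station`, `phase`,
#'   `truncated`), `head_m`, `heading`, `mirrored`.
#' @export
assemble_sampling_volume <- function(trace, head_m, heading = c(1, 0, 0),
                                     mirrored = FALSE) {
  if (!inherits(trace, "particle_trace") || nrow(trace$origins) == 0) {
    abort("assemble_sampling_volume: empty or invalid trace",
          class = "fanflow_data_error")
  }
  heading <- heading / vnorm(heading)
  origins <- tibble::tibble(
    cycles_to_arrival = trace$origins$cycles_back,
    x_m = trace$origins$x_m, y_m = trace$origins$y_m,
    z_m = trace$origins$z_m,
    station = trace$origins$station, phase = trace$origins$phase,
    truncated = trace$origins$truncated
  )
  structure(
    list(origins = origins, head_m = head_m, heading = heading,
         mirrored = mirrored),
    class = "sampling_volume"
  )
}

#' Mirror a single-wing sampling volume through the sagittal plane
#'
#' Adds the y-mirrored copy of every origin, turning a single-wing (half
#' domain) volume into the two-wing volume whose horizontal-angle
#' distribution is symmetric about dead ahead.
#'
#' @param volume A `sampling_volume`.
#' @return A mirrored `sampling_volume`.
#' @export
mirror_volume <- function(volume) {
  if (volume$mirrored) return(volume)
  m <- volume$origins
  m$y_m <- 2 * volume$head_m[2] - m$y_m
  volume$origins <- dplyr::bind_rows(volume$origins, m)
  volume$mirrored <- TRUE
  volume
}

#' @export
print.sampling_volume <- function(x, ...) {
  cat("<sampling_volume>\n")
  ok <- !x$origins$truncated
  cat(sprintf("  %d origin records (%d usable, %d truncated)%s\n",
              nrow(x$origins), sum(ok), sum(!ok),
              if (x$mirrored) ", mirrored (two wings)" else " (single wing)"))
  cat(sprintf("  arrival offsets: %d..%d cycles\n",
              min(x$origins$cycles_to_arrival),
              max(x$origins$cycles_to_arrival)))
  invisible(x)
}
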