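#' Construct a time-periodic gridded flow field
#'
#' Holds one converged wingbeat cycle of velocity snapshots on a structured
#' Cartesian grid, treated as exactly time-periodic. Snapshot `k` holds the
#' field at time `(k-1) T / S` for `S = n_snapshots`.
#'
#' @param u,v,w 4-D arrays `(nx, ny, nz, S)` of velocity components, m/s.
#' @param origin_m Grid origin (position of node `[1,1,1]`), metres.
#' @param spacing_m Grid spacing per axis (scalar or length 3), metres.
#' @param period_s Cycle period T, seconds.
#' @return Object of class `flow_field`.
#' @export
flow_field <- function(u, v, w, origin_m, spacing_m, period_s) {
  dims <- dim(u)
  if (length(dims) != 4) {
    abort("flow_field: u, v, w must be 4-D arrays (nx, ny, nz, S)",
          class = "fanflow_config_error")
  }
  if (!identical(dim(v), dims) || !identical(dim(w), dims)) {
    abort("flow_field: component array dimensions differ",
          class = "fanflow_config_error")
  }
  if (dims[4] < 4) {
    abort("flow_field: at least 4 snapshots required for third-order temporal interpolation",
          class = "fanflow_config_error")
  }
  if (length(spacing_m) == 1) spacing_m <- rep(spacing_m, 3)
  if (any(spacing_m <= 0) || period_s <= 0) {
    abort("flow_field: spacing_m and period_s must be > 0",
          class = "fanflow_config_error")
  }
  structure(
    list(u = u, v = v, w = w,
         origin_m = origin_m, spacing_m = spacing_m, period_s = period_s,
         dims = dims, n_snapshots = dims[4],
         box_max_m = origin_m + (dims[1:3] - 1) * spacing_m,
         periodic = TRUE),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field>\n")
  cat(sprintf("  grid %d x %d x %d, %d snapshots over T = %.4g s\n",
              x$dims[1], x$dims[2], x$dims[3], x$n_snapshots, x$period_s))
  cat(sprintf("  box [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] m\n",
              x$origin_m[1], x$box_max_m[1], x$origin_m[2], x$box_max_m[2],
              x$origin_m[3], x$box_max_m[3]))
  invisible(x)
}

# centered 4-node Lagrange weights at fractional offset mu in [0,1)
# for nodes at offsets -1, 0, 1, 2
lagrange4_weights <- function(mu) {
  cbind(
    -mu * (mu - 1) * (mu - 2) / 6,
    (mu + 1) * (mu - 1) * (mu - 2) / 2,
    -(mu + 1) * mu * (mu - 2) / 2,
    (mu + 1) * mu * (mu - 1) / 6
  )
}

#' Velocity at arbitrary space-time points
#'
#' Trilinear interpolation in space on each of the four temporally nearest
#' snapshots (with periodic wrap of the snapshot index), combined by
#' third-order (4-node) Lagrangian interpolation in time. Exact for fields
#' trilinear in space and cubic in time; exactly periodic in `time` with
#' period `field$period_s`.
#'
#' @param field A [flow_field()].
#' @param points n x 3 matrix (or length-3 vector) of positions, metres.
#' @param time Time in seconds: scalar, or vector of length n (one per
#'   point).
#' @param out_of_domain `"error"` aborts on the first point outside the grid
#'   box (the policy for tracing; the caller truncates); `"freeze"` clamps
#'   positions to the nearest boundary node (the policy for probing).
#' @return n x 3 matrix of velocities, m/s.
#' @export
velocity_at <- function(field, points, time,
                        out_of_domain = c("error", "freeze")) {
  out_of_domain <- match.arg(out_of_domain)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  lo <- field$origin_m
  hi <- field$box_max_m
  outside <- points[, 1] < lo[1] | points[, 1] > hi[1] |
    points[, 2] < lo[2] | points[, 2] > hi[2] |
    points[, 3] < lo[3] | points[, 3] > hi[3]
  if (any(outside)) {
    if (out_of_domain == "error") {
      i <- which(outside)[1]
      abort(sprintf(
        "velocity_at: point (%.4g, %.4g, %.4g) m outside the grid box",
        points[i, 1], points[i, 2], points[i, 3]
      ), class = "fanflow_domain_error")
    }
    points[, 1] <- pmin(pmax(points[, 1], lo[1]), hi[1])
    points[, 2] <- pmin(pmax(points[, 2], lo[2]), hi[2])
    points[, 3] <- pmin(pmax(points[, 3], lo[3]), hi[3])
  }

  # fractional grid coordinates and cell indices (clamped at the top face)
  dims <- field$dims
  gx <- (points[, 1] - lo[1]) / field$spacing_m[1]
  gy <- (points[, 2] - lo[2]) / field$spacing_m[2]
  gz <- (points[, 3] - lo[3]) / field$spacing_m[3]
  ix <- pmin(floor(gx), dims[1] - 2) + 1
  iy <- pmin(floor(gy), dims[2] - 2) + 1
  iz <- pmin(floor(gz), dims[3] - 2) + 1
  fx <- gx - (ix - 1)
  fy <- gy - (iy - 1)
  fz <- gz - (iz - 1)

  # temporal nodes and weights
  S <- field$n_snapshots
  dt <- field$period_s / S
  s <- (time / dt) %% S
  base <- floor(s)
  mu <- s - base
  tw <- lagrange4_weights(mu)
  if (length(time) == 1) {
    base <- rep(base, n)
    tw <- tw[rep(1, n), , drop = FALSE]
  } else if (length(time) != n) {
    abort("velocity_at: time must be a scalar or one value per point",
          class = "fanflow_config_error")
  }

  out <- matrix(0, n, 3)
  for (off in -1:2) {
    snap <- (base + off) %% S + 1
    w_t <- tw[, off + 2]
    for (dxi in 0:1) for (dyi in 0:1) for (dzi in 0:1) {
      w_s <- (if (dxi == 1) fx else 1 - fx) *
        (if (dyi == 1) fy else 1 - fy) *
        (if (dzi == 1) fz else 1 - fz)
      idx <- cbind(ix + dxi, iy + dyi, iz + dzi, snap)
      w <- w_t * w_s
      out[, 1] <- out[, 1] + w * field$u[idx]
      out[, 2] <- out[, 2] + w * field$v[idx]
      out[, 3] <- out[, 3] + w * field$w[idx]
    }
  }
  out
}

#' Probe the flow at a virtual antenna
#'
#' Samples the interpolated velocity at every antenna station over one
#' wingbeat cycle and summarises each station by the cycle-mean speed, the
#' oscillation amplitude (half the peak-to-peak range of the phase-averaged
#' speed series) and whether the dominant spectral component lies at the
#' wingbeat frequency f, at 2f, elsewhere, or nowhere (steady flow).
#'
#' @param field A [flow_field()].
#' @param antenna A [virtual_antenna()].
#' @param samples_per_cycle Temporal samples over one period.
#' @param out_of_domain Passed to [velocity_at()]; the default freezes
#'   out-of-box stations at the boundary (and they are reported).
#' @return Object of class `antenna_probe`: list with `series` (tibble:
#'   `station`, `arc_frac`, `t_hat`, `u`, `v`, `w`, `speed_m_s`) and
#'   `summary` (tibble: `station`, `arc_frac`, `mean_speed_m_s`,
#'   `amplitude_m_s`, `dominant`).
#' @export
probe_antenna <- function(field, antenna, samples_per_cycle = 200,
                          out_of_domain = c("freeze", "error")) {
  out_of_domain <- match.arg(out_of_domain)
  st <- antenna$stations
  n_st <- nrow(st)
  lo <- field$origin_m
  hi <- field$box_max_m
  bad <- which(st[, 1] < lo[1] | st[, 1] > hi[1] |
                 st[, 2] < lo[2] | st[, 2] > hi[2] |
                 st[, 3] < lo[3] | st[, 3] > hi[3])
  if (length(bad) > 0 && out_of_domain == "error") {
    abort(paste0("probe_antenna: antenna station(s) outside the domain: ",
                 paste(bad, collapse = ", ")),
          class = "fanflow_domain_error")
  }
  t_hat <- seq(0, 1, length.out = samples_per_cycle + 1)[seq_len(samples_per_cycle)]
  arc <- seq(0, 1, length.out = n_st)
  series <- purrr::map(seq_along(t_hat), function(j) {
    uvw <- velocity_at(field, st, t_hat[j] * field$period_s,
                       out_of_domain = "freeze")
    tibble::tibble(
      station = seq_len(n_st), arc_frac = arc, t_hat = t_hat[j],
      u = uvw[, 1], v = uvw[, 2], w = uvw[, 3],
      speed_m_s = sqrt(rowSums(uvw^2))
    )
  }) |> dplyr::bind_rows()

  summary <- series |>
    dplyr::group_by(.data$station, .data$arc_frac) |>
    dplyr::summarise(
      mean_speed_m_s = mean(.data$speed_m_s),
      amplitude_m_s = (max(.data$speed_m_s) - min(.data$speed_m_s)) / 2,
      dominant = dominant_harmonic(.data$speed_m_s),
      .groups = "drop"
    )
  structure(
    list(series = series, summary = summary, period_s = field$period_s,
         frozen_stations = bad),
    class = "antenna_probe"
  )
}

# classify the dominant oscillation of a one-cycle series: "f", "2f",
# "other", or "none" for a steady series
dominant_harmonic <- function(speed) {
  n <- length(speed)
  amp <- (max(speed) - min(speed)) / 2
  if (amp < 1e-12 * max(abs(speed), 1e-300)) return("none")
  Y <- Mod(fft(speed - mean(speed)))[2:max(2, floor(n / 2))]
  h <- which.max(Y)
  if (h == 1) "f" else if (h == 2) "2f" else "other"
}

#' @export
print.antenna_probe <- function(x, ...) {
  cat("<antenna_probe>\n")
  n_st <- max(x$summary$station)
  cat(sprintf("  %d stations, %d samples per cycle\n",
              n_st, nrow(x$series) / n_st))
  tip <- x$summary[which.max(x$summary$arc_frac), ]
  cat(sprintf("  tip station: mean %.3g m/s, amplitude %.3g m/s (dominant: %s)\n",
              tip$mean_speed_m_s, tip$amplitude_m_s, tip$dominant))
  invisible(x)
}

#' Write / read a flow field
#'
#' On-disk dialect: a long CSV of node velocities (`snapshot`, `ix`, `iy`,
#' `iz`, `u`, `v`, `w`) plus a JSON sidecar `<path>.json` with `dims`,
#' `origin_m`, `spacing_m` and `period_s`. Snapshot times are implicit and
#' uniform: `(k-1) * period_s / S`.
#'
#' @param field A [flow_field()].
#' @param path CSV path.
#' @return `write_flow_field()` returns `path` invisibly;
#'   `read_flow_field()` returns a [flow_field()].
#' @export
write_flow_field <- function(field, path) {
  dims <- field$dims
  grid <- expand.grid(ix = seq_len(dims[1]), iy = seq_len(dims[2]),
                      iz = seq_len(dims[3]), snapshot = seq_len(dims[4]))
  df <- data.frame(
    snapshot = grid$snapshot, ix = grid$ix, iy = grid$iy, iz = grid$iz,
    u = as.vector(aperm(field$u, c(1, 2, 3, 4))),
    v = as.vector(field$v), w = as.vector(field$w)
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(dims = dims, origin_m = field$origin_m,
         spacing_m = field$spacing_m, period_s = field$period_s),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(paste0("read_flow_field: missing sidecar ", meta_path),
          class = "fanflow_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("snapshot", "ix", "iy", "iz", "u", "v", "w")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("read_flow_field: ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "fanflow_format_error")
  }
  dims <- as.integer(meta$dims)
  ord <- order(df$snapshot, df$iz, df$iy, df$ix)
  df <- df[ord, ]
  flow_field(
    u = array(df$u, dims), v = array(df$v, dims), w = array(df$w, dims),
    origin_m = as.numeric(meta$origin_m),
    spacing_m = as.numeric(meta$spacing_m),
    period_s = as.numeric(meta$period_s)
  )
}
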