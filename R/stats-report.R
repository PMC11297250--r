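#' Head-relative particle coordinates
#'
#' Converts sampling-volume origins into the three headline coordinates:
#' distance from the head, horizontal angle (signed azimuth of the
#' head-to-origin vector from the resting heading, measured in the
#' horizontal plane, positive toward the animal's left — the side of the
#' simulated wing) and vertical angle (elevation of that vector above the
#' horizontal plane). Origins coincident with the head are excluded;
#' origins straight above/below the head have an undefined azimuth and get
#' `h_angle_deg = NA` (excluded from horizontal-angle summaries) while
#' keeping their vertical angle of +/-90 degrees.
#'
#' @param volume A `sampling_volume`.
#' @param include_truncated Include flagged (truncated) trajectories?
#' @return Tibble: `cycles_to_arrival`, `distance_m`, `h_angle_deg`,
#'   `v_angle_deg`, `station`, `phase`. The number of excluded
#'   head-coincident origins is attached as attribute `"n_excluded"`.
#' @export
head_relative_coordinates <- function(volume, include_truncated = FALSE) {
  o <- volume$origins
  if (!include_truncated) o <- o[!o$truncated, ]
  if (nrow(o) == 0) {
    abort("head_relative_coordinates: no usable origins",
          class = "fanflow_data_error")
  }
  d <- cbind(o$x_m - volume$head_m[1],
             o$y_m - volume$head_m[2],
             o$z_m - volume$head_m[3])
  dist <- sqrt(rowSums(d^2))
  coincident <- dist < 1e-12
  h <- volume$heading
  h[3] <- 0
  if (vnorm(h) == 0) {
    abort("head_relative_coordinates: heading has no horizontal component",
          class = "fanflow_geometry_error")
  }
  h <- h / vnorm(h)
  lat <- pracma_cross(c(0, 0, 1), h)  # positive toward the animal's left
  fwd <- as.vector(d %*% h)
  side <- as.vector(d %*% lat)
  horiz <- sqrt(fwd^2 + side^2)
  pole <- horiz < 1e-12
  out <- tibble::tibble(
    cycles_to_arrival = o$cycles_to_arrival,
    distance_m = dist,
    h_angle_deg = ifelse(pole, NA_real_, rad2deg(atan2(side, fwd))),
    v_angle_deg = rad2deg(atan2(d[, 3], horiz)),
    station = o$station, phase = o$phase
  )[!coincident, ]
  attr(out, "n_excluded") <- sum(coincident)
  out
}

#' Violin-style summary by arrival-time bin
#'
#' Per-bin order statistics in the convention of violin/box displays:
#' median, 25th/75th percentiles (linear interpolation of order statistics,
#' quantile type 7) and whiskers at the minimum and maximum after removing
#' Tukey outliers (points beyond 1.5 IQR outside the quartiles). Empty bins
#' are omitted with a warning.
#'
#' @param data A data frame (e.g. from [head_relative_coordinates()]).
#' @param value Name of the numeric column to summarise.
#' @param bin_col Name of the arrival-time column to bin on.
#' @param bin_width Bin width in cycles (bins are `(0,w], (w,2w], ...`,
#'   labelled by their upper edge).
#' @return Tibble: `arrival_bin`, `n`, `median`, `p25`, `p75`, `lo`, `hi`.
#' @export
violin_summary <- function(data, value, bin_col = "cycles_to_arrival",
                           bin_width = 5) {
  if (!value %in% names(data)) {
    abort(paste0("violin_summary: no column '", value, "'"),
          class = "fanflow_data_error")
  }
  df <- tibble::tibble(
    v = data[[value]],
    bin = ceiling(data[[bin_col]] / bin_width) * bin_width
  )
  n_na <- sum(is.na(df$v))
  df <- df[!is.na(df$v), ]
  if (nrow(df) == 0) {
    warn("violin_summary: no non-missing values")
    return(tibble::tibble(arrival_bin = integer(), n = integer(),
                          median = numeric(), p25 = numeric(),
                          p75 = numeric(), lo = numeric(), hi = numeric()))
  }
  out <- df |>
    dplyr::group_by(arrival_bin = .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$v),
      p25 = quantile(.data$v, 0.25, type = 7, names = FALSE),
      p75 = quantile(.data$v, 0.75, type = 7, names = FALSE),
      lo = {
        q1 <- quantile(.data$v, 0.25, type = 7, names = FALSE)
        q3 <- quantile(.data$v, 0.75, type = 7, names = FALSE)
        min(.data$v[.data$v >= q1 - 1.5 * (q3 - q1)])
      },
      hi = {
        q1 <- quantile(.data$v, 0.25, type = 7, names = FALSE)
        q3 <- quantile(.data$v, 0.75, type = 7, names = FALSE)
        max(.data$v[.data$v <= q3 + 1.5 * (q3 - q1)])
      },
      .groups = "drop"
    )
  out
}

#' Angular extent of the sampling volume
#'
#' Width of the smallest angular interval containing the given fraction of
#' particles (default 90%). For a mirrored two-wing volume the interval is
#' symmetric about dead ahead and the two-sided width is reported
#' (`2 * quantile(|angle|, coverage)`), which makes the two-wing extent
#' exactly twice the one-sided extent of a symmetric single-wing
#' distribution.
#'
#' @param h_angle_deg Horizontal angles in degrees, in (-180, 180].
#' @param coverage Fraction of particles the interval must contain.
#' @param mirrored Symmetrize about 0 degrees (two-wing volume)?
#' @return Extent in degrees.
#' @export
angular_extent <- function(h_angle_deg, coverage = 0.9, mirrored = FALSE) {
  a <- h_angle_deg[!is.na(h_angle_deg)]
  if (length(a) < 10) {
    abort("angular_extent: need at least 10 particles",
          class = "fanflow_data_error")
  }
  if (coverage <= 0 || coverage >= 1) {
    abort("angular_extent: coverage must be in (0, 1)",
          class = "fanflow_config_error")
  }
  if (mirrored) {
    return(2 * quantile(abs(a), coverage, type = 7, names = FALSE))
  }
  n <- length(a)
  a <- sort(a)
  m <- ceiling(coverage * n)
  if (m <= 1) return(0)
  # circular: allow windows that wrap through +/-180
  ext <- c(a, a + 360)
  i <- seq_len(n)
  min(ext[i + m - 1] - ext[i])
}

#' Kuiper test of angular uniformity
#'
#' Tests the horizontal-angle distribution against the uniform distribution
#' on the covered angular domain using Kuiper's statistic V = D+ + D-, the
#' rotation-invariant variant of Kolmogorov-Smirnov appropriate for angles.
#' A small p-value indicates an anisotropic sampling volume.
#'
#' @param h_angle_deg Angles in degrees.
#' @param domain Angular domain assumed under the null, degrees.
#' @return A list (class `htest`) with `statistic` (V), `p.value` and `n`.
#' @export
anisotropy_test <- function(h_angle_deg, domain = c(-180, 180)) {
  a <- h_angle_deg[!is.na(h_angle_deg)]
  n <- length(a)
  if (n < 50) {
    abort("anisotropy_test: need at least 50 particles",
          class = "fanflow_data_error")
  }
  u <- sort((a - domain[1]) / (domain[2] - domain[1]))
  if (any(u < 0 | u > 1)) {
    abort("anisotropy_test: angles outside the stated domain",
          class = "fanflow_config_error")
  }
  i <- seq_len(n)
  d_plus <- max(i / n - u)
  d_minus <- max(u - (i - 1) / n)
  V <- d_plus + d_minus
  lambda <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  if (lambda < 0.4) {
    p <- 1
  } else {
    j <- 1:100
    p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  structure(
    list(statistic = c(V = V), p.value = p, n = n,
         method = "Kuiper test of angular uniformity",
         data.name = deparse(substitute(h_angle_deg))),
    class = "htest"
  )
}
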