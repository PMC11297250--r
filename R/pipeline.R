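#' Default pipeline configuration
#'
#' The packaged end-to-end configuration: mean fanning kinematics, the
#' simplified induced-flow grid sized to hold ~40 wingbeats of backward
#' drift, the 21-station antenna and the reference tracing protocol
#' (21 phases, 500 steps/cycle, 40 cycles). Every field can be overridden
#' via the `config` argument of [run_pipeline()] or a YAML file.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    kinematics = list(),        # kinematics_spec() arguments
    noise_sd_m = 0,
    flow = list(
      box_min_m = c(-0.06, -0.09, -0.05),
      box_max_m = c(0.16, 0.09, 0.13),
      spacing_m = 0.006,
      snapshots_per_cycle = 50,
      entrainment = 0.25
    ),
    antenna = list(n_stations = 21),
    trace = list(
      n_release_phases = 21,
      steps_per_cycle = 500,
      n_cycles = 40,
      integrator = "euler"
    ),
    mirror = TRUE,
    probe_samples_per_cycle = 200,
    figures = TRUE
  )
}

# deep-merge override into base
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the configuration list; `read_config()` merges the
#' file over [default_config()] so partial files are valid.
#'
#' @param config A configuration list.
#' @param path YAML path.
#' @return `read_config()` returns the merged list.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("read_config: no such file: ", path),
          class = "fanflow_io_error")
  }
  merge_config(default_config(), yaml::read_yaml(path))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write a reconstructed-kinematics JSON
#'
#' Angle series on the averaged-cycle grid plus the scalar parameters, all
#' in degrees/Hz/metres (the reporting units).
#'
#' @param kin A `wing_kinematics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinematics_json <- function(kin, path) {
  payload <- list(
    scalars = as.list(glance(kin)),
    cycle = as.list(kin$cycle),
    alpha = if (!is.null(kin$alpha)) as.list(kin$alpha) else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Chains every stage from one configuration: synthetic landmark generation,
#' kinematic reconstruction, induced-flow synthesis, antenna probing,
#' backward particle tracing, sampling-volume statistics and the report.
#' All artifacts (landmark CSV, kinematics JSON, probe CSV, origin CSV,
#' stats CSV, report, provenance JSON) are written under `out_dir`. All
#' randomness flows through `config$seed`.
#'
#' @param config Configuration list (merged over [default_config()]) or the
#'   path of a YAML file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results (`kin`,
#'   `field`, `probe`, `trace`, `volume`, `config`, `paths`).
#' @export
run_pipeline <- function(config = list(), out_dir = "fanflow_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  spec <- do.call(kinematics_spec, config$kinematics)
  track <- generate_landmarks(spec, noise_sd = config$noise_sd_m,
                              seed = config$seed)
  landmarks_path <- file.path(out_dir, "landmarks.csv")
  write_landmarks(track, landmarks_path)

  kin <- reconstruct_kinematics(track)
  kin <- deconflict_sagittal(kin)
  kin_path <- file.path(out_dir, "kinematics.json")
  write_kinematics_json(kin, kin_path)

  fl <- config$flow
  grid_spec <- analytic_flow_spec(
    kind = "uniform",
    frequency_hz = kin$frequency_hz,
    box_min_m = as.numeric(fl$box_min_m),
    box_max_m = as.numeric(fl$box_max_m),
    spacing_m = fl$spacing_m,
    snapshots_per_cycle = fl$snapshots_per_cycle
  )
  field <- generate_induced_flow(kin, grid_spec,
                                 entrainment = fl$entrainment)

  # antenna from the (static) antenna landmarks of the left side
  ab <- track[track$landmark == "antenna_base" & track$side == "L", ]
  at <- track[track$landmark == "antenna_tip" & track$side == "L", ]
  antenna <- virtual_antenna(
    base_m = colMeans(as.matrix(ab[, c("x_m", "y_m", "z_m")])),
    tip_m = colMeans(as.matrix(at[, c("x_m", "y_m", "z_m")])),
    n_stations = config$antenna$n_stations
  )

  probe <- probe_antenna(field, antenna,
                         samples_per_cycle = config$probe_samples_per_cycle)
  probe_path <- file.path(out_dir, "probe.csv")
  utils::write.csv(as.data.frame(probe$series), probe_path, row.names = FALSE)

  cfg <- trace_config(
    n_release_phases = config$trace$n_release_phases,
    steps_per_cycle = config$trace$steps_per_cycle,
    n_cycles = config$trace$n_cycles,
    integrator = config$trace$integrator
  )
  trace <- backtrace(field, antenna, cfg)
  origins_path <- file.path(out_dir, "origins.csv")
  utils::write.csv(as.data.frame(trace$origins), origins_path,
                   row.names = FALSE)

  heads <- track[track$landmark == "head_tip", ]
  head_m <- colMeans(as.matrix(heads[, c("x_m", "y_m", "z_m")]))
  volume <- assemble_sampling_volume(trace, head_m = head_m)
  if (isTRUE(config$mirror)) volume <- mirror_volume(volume)

  stats_path <- file.path(out_dir, "stats.csv")
  write_stats_csv(volume, stats_path)
  report_path <- render_report(kin, probe, volume, dir = out_dir,
                               config = config,
                               figures = isTRUE(config$figures))

  provenance <- list(
    package = "fanflow",
    version = as.character(utils::packageVersion("fanflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = config_hash(config),
    outputs = list(
      landmarks = unname(tools::md5sum(landmarks_path)),
      kinematics = unname(tools::md5sum(kin_path)),
      probe = unname(tools::md5sum(probe_path)),
      origins = unname(tools::md5sum(origins_path)),
      stats = unname(tools::md5sum(stats_path))
    )
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(kin = kin, field = field, probe = probe, trace = trace,
                 volume = volume, config = config,
                 paths = list(landmarks = landmarks_path, kinematics = kin_path,
                              probe = probe_path, origins = origins_path,
                              stats = stats_path, report = report_path)))
}

#' Validate an on-disk artifact against its dialect
#'
#' Checks the named format and lists every violation found (never stopping
#' at the first): required columns, non-empty records, numeric ranges, and
#' for flow fields the sidecar metadata and complete uniform snapshot
#' indexing.
#'
#' @param path File to validate.
#' @param format One of `"landmarks"`, `"flow_field"`, `"stats"`.
#' @return Tibble with columns `rule` and `message`; zero rows means valid.
#' @export
validate_format <- function(path, format = c("landmarks", "flow_field",
                                             "stats")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("validate_format: no such file: ", path),
          class = "fanflow_io_error")
  }
  v <- list()
  add <- function(rule, message) {
    v[[length(v) + 1]] <<- tibble::tibble(rule = rule, message = message)
  }
  df <- tryCatch(utils::read.csv(path), error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    add("no_records", paste0(path, ": no records"))
    return(dplyr::bind_rows(v))
  }
  req <- switch(format,
    landmarks = c("time_s", "side", "landmark", "x_m", "y_m", "z_m"),
    flow_field = c("snapshot", "ix", "iy", "iz", "u", "v", "w"),
    stats = c("arrival_bin", "metric", "median", "p25", "p75", "lo", "hi", "n")
  )
  for (col in setdiff(req, names(df))) {
    add("missing_column", paste0(path, ": missing column ", col))
  }
  if (length(setdiff(req, names(df))) > 0) return(dplyr::bind_rows(v))

  if (format == "landmarks") {
    if (!all(df$side %in% c("L", "R", "C"))) {
      add("bad_side", "side values must be L, R or C")
    }
    for (col in c("time_s", "x_m", "y_m", "z_m")) {
      if (any(!is.finite(df[[col]]))) {
        add("non_finite", paste0("non-finite values in ", col))
      }
    }
    if (is.unsorted(unique(df$time_s))) {
      add("unsorted_time", "time_s blocks are not in increasing order")
    }
  } else if (format == "flow_field") {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path)) {
      add("missing_sidecar", paste0("missing sidecar ", meta_path))
    } else {
      meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                       error = function(e) NULL)
      if (is.null(meta) ||
            !all(c("dims", "origin_m", "spacing_m", "period_s") %in%
                   names(meta))) {
        add("bad_sidecar", "sidecar must carry dims, origin_m, spacing_m, period_s")
      } else {
        dims <- as.integer(meta$dims)
        if (dims[4] < 4) {
          add("too_few_snapshots", "at least 4 snapshots are required")
        }
        if (nrow(df) != prod(dims)) {
          add("incomplete_grid", sprintf(
            "expected %d rows for dims %s, found %d (snapshot times must be uniform over one period: every node of every snapshot present exactly once)",
            prod(dims), paste(dims, collapse = "x"), nrow(df)))
        }
        snaps <- sort(unique(df$snapshot))
        if (!identical(as.integer(snaps), seq_len(dims[4]))) {
          add("bad_snapshot_index",
              "snapshot indices must be 1..S (uniform spacing over the period)")
        }
      }
    }
    for (col in c("u", "v", "w")) {
      if (any(!is.finite(df[[col]]))) {
        add("non_finite", paste0("non-finite values in ", col))
      }
    }
  } else if (format == "stats") {
    bad <- with(df, !(lo <= p25 & p25 <= median & median <= p75 & p75 <= hi))
    if (any(bad)) {
      add("order_statistics",
          paste0("rows with lo <= p25 <= median <= p75 <= hi violated: ",
                 paste(which(bad), collapse = ", ")))
    }
    if (any(df$n <= 0)) add("empty_bin", "reported bins must have n > 0")
  }
  dplyr::bind_rows(v)
}
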