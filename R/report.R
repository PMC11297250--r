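# minimal markdown table
md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write the combined stats CSV
#'
#' One row per arrival-time bin and metric (`distance` in mm, `h_angle` and
#' `v_angle` in degrees) with the violin summary columns.
#'
#' @param volume A `sampling_volume`.
#' @param path Output CSV path.
#' @param bin_width Arrival-time bin width in cycles.
#' @return The stats tibble, invisibly written to `path`.
#' @export
write_stats_csv <- function(volume, path, bin_width = 5) {
  hr <- head_relative_coordinates(volume)
  hr$distance_mm <- 1e3 * hr$distance_m
  metrics <- c(distance = "distance_mm", h_angle = "h_angle_deg",
               v_angle = "v_angle_deg")
  stats <- purrr::imap(metrics, function(col, met) {
    vs <- violin_summary(hr, col, bin_width = bin_width)
    vs$metric <- met
    vs
  }) |> dplyr::bind_rows() |>
    dplyr::select(dplyr::all_of(c("arrival_bin", "metric", "median", "p25",
                                  "p75", "lo", "hi", "n")))
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(stats)
}

#' Render the analysis report
#'
#' Writes a single markdown document summarising a run — averaged wing
#' angles, induced-flow probe, violin summaries of the sampling volume and
#' its anisotropy — plus PNG figures, into `dir`. The markdown body is
#' deterministic (no timestamps), so identical runs give byte-identical
#' reports.
#'
#' @param kin A `wing_kinematics` (or `NULL`).
#' @param probe An `antenna_probe` (or `NULL`).
#' @param volume A `sampling_volume` (or `NULL`; an empty volume produces an
#'   explicit notice).
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list echoed into the report.
#' @param figures Write PNG figures?
#' @return Path of the markdown report, invisibly.
#' @export
render_report <- function(kin = NULL, probe = NULL, volume = NULL,
                          dir = ".", config = NULL, figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(dir, "figures")
  if (figures) dir.create(fig_dir, showWarnings = FALSE)
  lines <- c("# Wing-fanning flow and sampling-volume report", "")

  save_fig <- function(plot, name) {
    if (!figures) return(invisible(NULL))
    ggplot2::ggsave(file.path(fig_dir, name), plot,
                    width = 6, height = 4, dpi = 150)
    invisible(NULL)
  }

  if (!is.null(kin)) {
    lines <- c(lines, "## Wing kinematics", "",
               md_table(glance(kin)), "")
    save_fig(autoplot(kin), "wing_angles.png")
    if (!is.null(kin$alpha)) {
      aoa <- angle_of_attack_series(kin)
      p <- ggplot2::ggplot(aoa, ggplot2::aes(x = .data$t_hat,
                                             y = .data$aoa_folded_deg,
                                             colour = factor(.data$station))) +
        downstroke_shade() +
        ggplot2::geom_line() +
        ggplot2::labs(x = "stroke cycle", y = "angle of attack (deg, folded)",
                      colour = "r/R") +
        ggplot2::theme_minimal()
      save_fig(p, "angle_of_attack.png")
      lines <- c(lines, "Figures: `figures/wing_angles.png`, `figures/angle_of_attack.png`.", "")
    } else {
      lines <- c(lines, "Figure: `figures/wing_angles.png`.", "")
    }
  }

  if (!is.null(probe)) {
    lines <- c(lines, "## Induced flow at the antenna", "",
               md_table(probe$summary), "")
    save_fig(autoplot(probe), "antenna_probe.png")
    lines <- c(lines, "Figure: `figures/antenna_probe.png`.", "")
  }

  if (!is.null(volume)) {
    usable <- sum(!volume$origins$truncated)
    if (usable == 0) {
      lines <- c(lines, "## Sampling volume", "",
                 "No particles: every trajectory was truncated at the domain boundary.", "")
    } else {
      lines <- c(lines, "## Sampling volume", "",
                 md_table(glance(volume)), "")
      hr <- head_relative_coordinates(volume)
      hr$distance_mm <- 1e3 * hr$distance_m
      for (m in c("distance_mm", "h_angle_deg", "v_angle_deg")) {
        vs <- violin_summary(hr, m)
        lines <- c(lines, paste0("### ", m), "", md_table(vs), "")
      }
      for (w in c("distance", "h_angle", "v_angle")) {
        save_fig(autoplot(volume, which = w), paste0("volume_", w, ".png"))
      }
      # top view of the origin cloud (the spatial footprint of the volume)
      p <- ggplot2::ggplot(
        dplyr::filter(volume$origins, !.data$truncated),
        ggplot2::aes(x = 1e3 * .data$x_m, y = 1e3 * .data$y_m,
                     colour = .data$cycles_to_arrival)
      ) +
        ggplot2::geom_point(size = 0.5, alpha = 0.6) +
        ggplot2::coord_equal() +
        ggplot2::scale_colour_viridis_c(name = "cycles to arrival") +
        ggplot2::labs(x = "x (mm, anterior)", y = "y (mm, left)",
                      title = "Particle origins, top view") +
        ggplot2::theme_minimal()
      save_fig(p, "volume_topview.png")
      lines <- c(lines,
                 "Figures: `figures/volume_distance.png`, `figures/volume_h_angle.png`, `figures/volume_v_angle.png`, `figures/volume_topview.png`.",
                 "")
    }
  }

  if (!is.null(config)) {
    lines <- c(lines, "## Configuration", "", "```yaml",
               strsplit(yaml::as.yaml(config), "\n")[[1]], "```", "")
  }

  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
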