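# End-to-end pipeline runners with reproducible configuration and a manifest
# per run. Also the backing for the command-line interface in
# inst/scripts/rodpol.

#' Default pipeline configuration
#'
#' All thresholds at their standard values: cluster detection at 2 SD above
#' the mean cytoplasmic fluorescence with a minimum size of 3 pixels, omega
#' bins at 0.9 and 0.2, polar caps spanning 1/6 of the axis length, and
#' reversal detection at a 120-degree turn with 0.03 um minimum step.
#'
#' @return Named list of defaults; override any entry via [load_config()] or
#'   by editing the returned list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # scene simulation
    n_cells = 50L,
    image_shape = c(512L, 512L),
    pixel_size = 0.06,
    cell_length_range = c(5, 7),
    cell_width = 0.5,
    total_intensity = 5e4,
    pole1_fraction = 0.35,
    pole2_fraction = 0.15,
    cluster_sigma = 1.8,
    background_level = 100,
    read_noise_sd = 2,
    shot_noise = TRUE,
    # quantification
    cap_extent = 1 / 6,
    k_sd = 2,
    min_size = 3L,
    bins = c(0.9, 0.2),
    subtract_cytoplasm = FALSE,
    sd_type = "population",
    exclude_border = TRUE,
    pooling = "replicate",
    # tracks
    n_tracks = 30L,
    speed = 2,
    frame_interval = 30,
    duration = 15,
    reversals_per_track = 2L,
    positional_noise_sd = 0.05,
    window = 15,
    angle_threshold = 120,
    min_step = 0.03
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Unspecified entries fall back to [default_config()]; unknown entries are
#' rejected so typos do not silently revert to defaults.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return Named configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config entries: %s.", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(cfg, user)
}

write_manifest <- function(out_dir, subcommand, config, inputs = character()) {
  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("rodpol")),
    r_version = as.character(getRversion()),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(manifest)
}

#' Simulate a scene and trajectories to disk
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory; a run manifest is written alongside the
#'   scene and track files.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- scene_spec(n_cells = config$n_cells,
                     image_shape = config$image_shape,
                     pixel_size = config$pixel_size,
                     cell_length_range = config$cell_length_range,
                     cell_width = config$cell_width,
                     seed = config$seed)
  loc <- localization_spec(total_intensity = config$total_intensity,
                           pole1_fraction = config$pole1_fraction,
                           pole2_fraction = config$pole2_fraction,
                           cluster_sigma = config$cluster_sigma,
                           background_level = config$background_level,
                           read_noise_sd = config$read_noise_sd,
                           shot_noise = config$shot_noise)
  scene <- generate_scene(spec, loc)
  write_scene(scene, out_dir)
  ts <- track_spec(n_tracks = config$n_tracks, speed = config$speed,
                   frame_interval = config$frame_interval,
                   duration = config$duration,
                   positional_noise_sd = config$positional_noise_sd,
                   seed = config$seed + 1L)
  ts$reversal_times <- replicate(
    config$n_tracks,
    draw_reversal_times(config$reversals_per_track, config$duration,
                        config$frame_interval),
    simplify = FALSE)
  write_tracks(generate_tracks(ts), out_dir)
  write_manifest(out_dir, "simulate", config)
  invisible(file.path(out_dir, c("mask.tif", "fluorescence.tif", "truth.csv",
                                 "tracks.csv", "track_truth.csv")))
}

#' Quantify polar fluorescence for mask/image pairs
#'
#' @param config Configuration list.
#' @param mask_paths,image_paths Parallel vectors of mask and fluorescence
#'   image paths; element i of each is one replicate/field pair.
#' @param out_dir Output directory for `cells.csv`, `population_summary.csv`,
#'   `scatter.csv` and the run manifest.
#' @return The per-cell `rodpol_quant` tibble (with a `replicate` column),
#'   invisibly.
#' @export
run_quantify <- function(config = default_config(), mask_paths, image_paths,
                         out_dir) {
  if (length(mask_paths) != length(image_paths)) {
    abort("`mask_paths` and `image_paths` must pair up one to one.")
  }
  exists_ok <- file.exists(mask_paths) & file.exists(image_paths)
  if (any(!exists_ok)) {
    warn(sprintf("Skipping missing pair(s): %s.",
                 paste(mask_paths[!exists_ok], collapse = ", ")))
    mask_paths <- mask_paths[exists_ok]
    image_paths <- image_paths[exists_ok]
  }
  if (length(mask_paths) == 0L) abort("No mask/image pairs to quantify.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_pair <- purrr::map2(mask_paths, image_paths, function(mp, ip) {
    mask <- read_labeled_mask(mp)
    image <- read_fluorescence_image(ip)
    quantify_cells(image, mask,
                   cap_extent = config$cap_extent, k_sd = config$k_sd,
                   min_size = config$min_size, bins = config$bins,
                   subtract_cytoplasm = config$subtract_cytoplasm,
                   sd_type = config$sd_type,
                   exclude_border = config$exclude_border)
  })
  cells <- dplyr::bind_rows(
    setNames(per_pair, basename(mask_paths)), .id = "replicate")
  class(cells) <- c("rodpol_quant", setdiff(class(cells), "rodpol_quant"))
  pop <- aggregate_population(cells, replicate = "replicate",
                              pooling = config$pooling)
  sc <- scatter_table(cells, replicate = "replicate")
  utils::write.csv(dplyr::select(
    cells, "replicate", "label", "total", "pole1_pct", "pole2_pct",
    "cytoplasmic_pct", "omega", "category"),
    file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(pop, file.path(out_dir, "population_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(sc, file.path(out_dir, "scatter.csv"), row.names = FALSE)
  write_manifest(out_dir, "quantify", config, c(mask_paths, image_paths))
  invisible(cells)
}

#' Aggregate an existing per-cell table
#'
#' @param config Configuration list.
#' @param cells_csv Path to a `cells.csv` written by [run_quantify()].
#' @param out_dir Output directory for `population_summary.csv`.
#' @return The `rodpol_popsummary` tibble, invisibly.
#' @export
run_aggregate <- function(config = default_config(), cells_csv, out_dir) {
  cells <- as_tibble(utils::read.csv(cells_csv))
  cells$category <- factor(cells$category, levels = LOCALIZATION_LEVELS)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- aggregate_population(cells, replicate = "replicate",
                              pooling = config$pooling)
  utils::write.csv(pop, file.path(out_dir, "population_summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "aggregate", config, cells_csv)
  invisible(pop)
}

#' Compute motility metrics from a trajectory CSV
#'
#' @param config Configuration list.
#' @param tracks_csv Path to a CSV with columns `cell`, `time_s`, `x_um`,
#'   `y_um`.
#' @param out_dir Output directory for `motility_per_cell.csv`,
#'   `motility_summary.csv` and the run manifest.
#' @return The per-cell `rodpol_motility` tibble, invisibly.
#' @export
run_tracks <- function(config = default_config(), tracks_csv, out_dir) {
  tracks <- as_tibble(utils::read.csv(tracks_csv))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  moving <- filter_moving(tracks, min_step = config$min_step)
  if (nrow(moving) == 0L) abort("No cells moved for the entire recording.")
  per_cell <- summarize_motility(moving, interval = config$frame_interval,
                                 window = config$window,
                                 angle_threshold = config$angle_threshold,
                                 min_step = config$min_step)
  summary <- aggregate_motility(per_cell)
  utils::write.csv(per_cell, file.path(out_dir, "motility_per_cell.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "motility_summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "tracks", config, tracks_csv)
  invisible(per_cell)
}
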