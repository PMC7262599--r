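# Pipeline driver: one configuration object carrying every stage parameter
# (defaults follow the published recipe where the recipe fixes a value:
# DoG sigmas 1.5/4.5 px, 15-px minimum spot size, 0.7 circularity cutoff,
# 3-px EB3 search radius) and a composition of detect -> segment -> track ->
# metrics over a stack.

#' Pipeline configuration
#'
#' Collects the tunable parameters of all stages with documented defaults.
#'
#' @param pixel_size,frame_interval calibration overrides (um/px, min).
#' @param dog_r_small,dog_r_large DoG sigmas (px).
#' @param min_spot_size minimum spot area (px).
#' @param circ_min circularity cutoff; lower regions are discarded.
#' @param track_mode linking model: nearest, drift or kalman.
#' @param search_radius_um centrosome linking radius per frame (um).
#'   Centrosome speeds of 0.1-0.5 um/min at 5-min frames give per-frame
#'   displacements up to 2.5 um, far beyond the 3-px radius appropriate
#'   for EB3 comets imaged at second-scale intervals; the default covers
#'   that speed range.
#' @param eb3_search_radius_px EB3 linking radius (px).
#' @param max_gap frames a track may skip.
#' @param min_track_length shortest track kept (points).
#' @param contact_threshold um below which centrosomes count as joined.
#' @param onset_threshold um above which separation has begun.
#' @param dwell,persistence consecutive-frame requirements for contact and
#'   onset calls.
#' @param ne_tol NE contact tolerance (um).
#' @param pause_window NE pause window (min).
#' @param seed RNG seed recorded in the run manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = NULL, frame_interval = NULL,
                            dog_r_small = 1.5, dog_r_large = 4.5,
                            min_spot_size = 15, circ_min = 0.7,
                            track_mode = "kalman",
                            search_radius_um = 2.5,
                            eb3_search_radius_px = 3,
                            max_gap = 1, min_track_length = 5,
                            contact_threshold = 1.5, onset_threshold = 2.5,
                            dwell = 2, persistence = 2,
                            ne_tol = 1, pause_window = 20, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   path)
  invisible(path)
}

#' Run the full analysis pipeline on a stack
#'
#' Detects centrosome spots per frame, segments nuclei (and the cell when a
#' tubulin channel is present), links spots into tracks, assigns the
#' centrosome pair of each nucleus and computes the pair metrics. A run
#' manifest (configuration hash, seed, package version, stage counts) makes
#' runs reproducible and auditable; identical config and input give
#' identical outputs.
#'
#' @param stack an `image_stack` with at least a `centrosome` channel;
#'   nucleus-referenced metrics additionally need a `dna` channel.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes spots.csv, geometry.csv,
#'   tracks.csv, metrics.csv and manifest.yaml.
#' @return list: `spots`, `geometry`, `tracks`, `pair`, `metrics`,
#'   `summary` (one-row data.frame of the headline per-cell numbers),
#'   `manifest`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!"centrosome" %in% stack$channels)
    stop("configuration error: stack has no 'centrosome' channel role",
         call. = FALSE)
  psz <- config$pixel_size %||% stack$pixel_size
  dt <- config$frame_interval %||% stack$frame_interval

  spots <- detect_stack(stack, "centrosome",
                        r_small = config$dog_r_small,
                        r_large = config$dog_r_large,
                        min_size = config$min_spot_size,
                        circ_min = config$circ_min)

  seg <- if ("dna" %in% stack$channels) segment_stack(stack) else NULL

  sp <- data.frame(frame = spots$frame, x = spots$x_um, y = spots$y_um,
                   intensity = spots$peak, spot_id = seq_len(nrow(spots)))
  tracks <- link_spots(sp, mode = config$track_mode,
                       search_radius = config$search_radius_um,
                       max_gap = config$max_gap)
  tracks <- merge(tracks, sp[, c("spot_id", "intensity")], by = "spot_id")
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  kept <- filter_tracks(tracks, min_length = config$min_track_length,
                        max_gaps = config$max_gap)

  nuc_mask <- if (!is.null(seg)) {
    labs <- seg$nucleus_masks[[1]]
    if (max(labs) >= 1) labs == 1 else NULL
  } else NULL
  pair <- assign_pair(kept)
  metrics <- if (pair$ok)
    pair_metrics(pair, geometry = seg$geometry,
                 nucleus_mask = nuc_mask, pixel_size = psz,
                 frame_interval = dt,
                 contact_threshold = config$contact_threshold,
                 onset_threshold = config$onset_threshold,
                 dwell = config$dwell,
                 persistence = config$persistence) else NULL

  summary <- data.frame(
    n_spots = nrow(spots),
    n_tracks = length(unique(kept$track_id)),
    analyzable = pair$ok,
    final_distance_um = if (pair$ok) metrics$distance$d_um[nrow(metrics$distance)] else NA,
    final_angle_deg = if (pair$ok) metrics$final_angle %||% NA else NA,
    congressed = if (pair$ok) metrics$contact$congressed else NA,
    contact_t_min = if (pair$ok) metrics$contact$contact_t_min else NA)

  manifest <- list(package_version = as.character(utils::packageVersion("centrotrack")),
                   config_hash = config_hash(unclass(config)),
                   seed = config$seed,
                   counts = list(spots = nrow(spots),
                                 tracks_kept = length(unique(kept$track_id)),
                                 cells = if (is.null(seg)) 0L else
                                   length(unique(seg$geometry$cell_id))))
  message(sprintf("[pipeline] spots=%d tracks=%d analyzable=%s",
                  nrow(spots), length(unique(kept$track_id)), pair$ok))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_units_csv(spots, file.path(out_dir, "spots.csv"),
                    "units: x/y in px and um, area in px, t in min")
    if (!is.null(seg))
      write_units_csv(seg$geometry, file.path(out_dir, "geometry.csv"),
                      "units: centroids in um")
    write_units_csv(kept, file.path(out_dir, "tracks.csv"),
                    "units: x/y in um, frames 1-based")
    write_units_csv(summary, file.path(out_dir, "metrics.csv"),
                    "units: distances in um, angles in deg, t in min")
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(spots = spots, geometry = if (is.null(seg)) NULL else seg$geometry,
       tracks = kept, pair = pair, metrics = metrics, summary = summary,
       manifest = manifest)
}

#' Simulate, render and write a synthetic movie with ground truth
#'
#' The simulate entry point: builds the scene, simulates the pair, renders
#' the stack and writes movie.tif (+ sidecar), truth.csv and scene.yaml to
#' a directory.
#'
#' @param config a [scene_config()].
#' @param program a [trajectory_program()].
#' @param out_dir output directory.
#' @return list with `stack` and `truth`, invisibly.
#' @export
simulate_to_dir <- function(config, program, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- make_scene(config)
  truth <- simulate_pair(program, scene, n_frames = config$n_frames,
                         frame_interval = config$frame_interval,
                         seed = config$seed)
  stack <- render_movie(scene, truth, config)
  write_stack(stack, file.path(out_dir, "movie.tif"))
  write_units_csv(as.data.frame(truth), file.path(out_dir, "truth.csv"),
                  "units: x/y/z in um, t in min")
  write_pipeline_config_scene(config, file.path(out_dir, "scene.yaml"))
  invisible(list(stack = stack, truth = truth))
}

write_pipeline_config_scene <- function(config, path) {
  vals <- unclass(config)
  vals$cell_polygon <- NULL
  vals$amplitudes <- as.list(vals$amplitudes)
  yaml::write_yaml(vals, path)
  invisible(path)
}
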