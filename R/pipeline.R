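#' Pipeline configuration
#'
#' Aggregates the calibration and all stage parameters of the tracking
#' workflow. Defaults encode the workflow's printed parameters: 0.1%
#' saturated pixels, 30 um blob diameter, quality threshold 25, 50 um
#' linking and gap-closing distances, frame gap 8.
#'
#' @param calibration A [calibration()].
#' @param preprocess A [preprocess_params()].
#' @param detection A [detection_params()].
#' @param linking A [linking_params()].
#' @param filter A [track_filter()].
#' @param subsample Optional number of tracks to subsample for outputs.
#' @param subsample_seed Seed for subsampling.
#' @param condition_label Label carried through to summaries.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(calibration = celltrax::calibration(2, 2),
                            preprocess = preprocess_params(),
                            detection = detection_params(),
                            linking = linking_params(),
                            filter = track_filter(),
                            subsample = NULL,
                            subsample_seed = 1L,
                            condition_label = "condition") {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(detection, "detection_params"),
            inherits(linking, "linking_params"),
            inherits(filter, "track_filter"))
  structure(list(calibration = as_calibration(calibration),
                 preprocess = preprocess, detection = detection,
                 linking = linking, filter = filter,
                 subsample = subsample, subsample_seed = subsample_seed,
                 condition_label = condition_label),
            class = "pipeline_config")
}

#' Run the full tracking workflow on one stack
#'
#' Preprocess, detect, link, close gaps, filter, summarize. Writes the
#' processed stack, the detections and track tables (both layouts), the
#' overlay video, motility summary CSVs, the origin-aligned trajectory and
#' MSD figures, and a machine-readable run log with every parameter.
#'
#' @param config A [pipeline_config()].
#' @param input A `celltrax_stack` or a TIFF path.
#' @param out_dir Output directory (created if missing).
#' @param preprocess Set `FALSE` if `input` is already background-subtracted
#'   and contrast-normalized.
#' @return A result bundle (list): `tracks`, `spots`, `summary`, `paths`;
#'   invisibly.
#' @export
run_pipeline <- function(config, input, out_dir, preprocess = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  stack <- stage("read", {
    if (inherits(input, "celltrax_stack")) input
    else read_stack(input, config$calibration)
  })
  message(sprintf("stack: %d frames %d x %d px", n_frames(stack),
                  dim(stack)[1], dim(stack)[2]))
  processed <- if (preprocess) {
    stage("preprocess", preprocess_stack(stack, config$preprocess))
  } else stack
  spots <- stage("detect", detect_spots(processed, config$detection))
  message(sprintf("detected %d spots (%.1f per frame)", nrow(spots),
                  nrow(spots) / n_frames(stack)))
  segments <- stage("link", link_frames(spots, config$linking))
  tracks <- stage("gap_close", close_gaps(segments, config$linking))
  message(sprintf("%d segments -> %d tracks",
                  dplyr::n_distinct(segments$segment_id), n_tracks(tracks)))
  tracks <- stage("filter", filter_tracks(tracks, config$filter))
  if (!is.null(config$subsample)) {
    tracks <- stage("subsample",
                    subsample_tracks(tracks, config$subsample,
                                     config$subsample_seed))
  }
  if (nrow(tracks) == 0L) abort("pipeline produced no tracks")
  summary <- stage("stats",
                   summarize_motility(tracks, config$calibration,
                                      label = config$condition_label,
                                      out_dir = out_dir))
  paths <- list(
    processed = file.path(out_dir, "processed.tif"),
    spots = file.path(out_dir, "spots.csv"),
    tracks = file.path(out_dir, "tracks.csv"),
    tracks_diper = file.path(out_dir, "tracks_diper.csv"),
    overlay = file.path(out_dir, "overlay.tif"),
    origin_plot = file.path(out_dir, "plot_at_origin.png"),
    msd_plot = file.path(out_dir, "msd.png"),
    run_log = file.path(out_dir, "run_log.yaml")
  )
  stage("write", {
    write_stack(processed, paths$processed)
    write_spots_table(dplyr::mutate(spots, track_id = -1L), paths$spots)
    write_spots_table(tracks, paths$tracks, layout = "spots_in_tracks")
    write_spots_table(tracks, paths$tracks_diper, layout = "diper")
    render_overlay(processed, tracks, paths$overlay)
    n_plot <- min(n_tracks(tracks), 256L)
    plot_at_origin(subsample_tracks(tracks, n_plot, config$subsample_seed),
                   file = paths$origin_plot)
    ggplot2::ggsave(paths$msd_plot, autoplot(summary), width = 5, height = 4)
    yaml::write_yaml(run_log(config, stack, spots, tracks), paths$run_log)
  })
  invisible(list(tracks = tracks, spots = spots, summary = summary,
                 paths = paths))
}

run_log <- function(config, stack, spots, tracks) {
  list(
    calibration = unclass(config$calibration),
    preprocess = unclass(config$preprocess),
    detection = unclass(config$detection),
    linking = unclass(config$linking),
    filter = lapply(unclass(config$filter), function(v) v %||% "none"),
    subsample = config$subsample %||% "none",
    subsample_seed = config$subsample_seed,
    condition_label = config$condition_label,
    counts = list(frames = n_frames(stack), spots = nrow(spots),
                  spots_per_frame = nrow(spots) / n_frames(stack),
                  tracks = n_tracks(tracks))
  )
}

#' Generate a synthetic fixture from a YAML config
#'
#' Reads a [simulation_config()] YAML (schema violations are reported by
#' field name) and writes the rendered stack, ground-truth table and config
#' copy via [make_fixture()].
#'
#' @param config_path YAML path.
#' @param out_dir Output directory.
#' @return Fixture paths, invisibly.
#' @export
run_simulation <- function(config_path, out_dir) {
  config <- read_simulation_config(config_path)
  make_fixture(config, out_dir)
}
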