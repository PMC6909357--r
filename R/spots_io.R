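#' Trajectory tables
#'
#' Tracks are held as a tidy tibble with one row per spot and columns
#' `track_id`, `frame` (0-based), `x`, `y` (micrometres) and `quality`
#' (detector response; `NA` when unknown). Two on-disk CSV layouts are
#' supported:
#'
#' * `"spots_in_tracks"`: header
#'   `TRACK_ID,SPOT_ID,FRAME,POSITION_X,POSITION_Y,QUALITY`, one row per spot,
#'   sorted by track then frame — the layout of a tracking tool's
#'   "spots in tracks statistics" export.
#' * `"diper"`: columns `TOTAL_TRACKS,FRAME,POSITION_X,POSITION_Y` with all
#'   trajectories concatenated contiguously (no blank rows) and the total
#'   track count stored in the first data row — the layout consumed by
#'   DiPer-style quantification macros.
#'
#' Both use comma separators, `.` decimal marks, LF line endings and UTF-8,
#' and round-trip coordinates losslessly to well over 9 significant digits.
#'
#' @name spots_tables
NULL

validate_tracks <- function(tracks, require_two = TRUE) {
  need <- c("track_id", "frame", "x", "y")
  if (!is.data.frame(tracks) || !all(need %in% names(tracks))) {
    abort("tracks must be a data frame with columns track_id, frame, x, y")
  }
  if (nrow(tracks) == 0L) abort("track table is empty")
  if (!"quality" %in% names(tracks)) tracks$quality <- NA_real_
  tracks <- tibble::as_tibble(tracks)[, c("track_id", "frame", "x", "y", "quality")] |>
    dplyr::arrange(.data$track_id, .data$frame)
  # track_id < 0 marks unlinked detections; per-track invariants don't apply
  bad <- tracks |>
    dplyr::filter(.data$track_id >= 0) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mono = all(diff(.data$frame) > 0),
                     n = dplyr::n(), .groups = "drop")
  if (any(!bad$mono)) {
    abort(sprintf("frames are not strictly increasing within track %s",
                  bad$track_id[!bad$mono][1]))
  }
  if (require_two && any(bad$n < 2L)) {
    abort(sprintf("track %s has fewer than 2 spots",
                  bad$track_id[bad$n < 2L][1]))
  }
  tracks
}

#' Count tracks in a trajectory table
#' @param tracks A tracks tibble.
#' @return Number of distinct `track_id` values.
#' @export
n_tracks <- function(tracks) dplyr::n_distinct(tracks$track_id)

#' Write a trajectory table
#'
#' @param tracks Tracks tibble (see [spots_tables]).
#' @param path Output CSV path.
#' @param layout `"spots_in_tracks"` or `"diper"`.
#' @return The path, invisibly.
#' @export
write_spots_table <- function(tracks, path,
                              layout = c("spots_in_tracks", "diper")) {
  layout <- match.arg(layout)
  tracks <- validate_tracks(tracks, require_two = FALSE) |>
    dplyr::arrange(.data$track_id, .data$frame)
  if (layout == "spots_in_tracks") {
    out <- tibble::tibble(
      TRACK_ID = tracks$track_id,
      SPOT_ID = seq_len(nrow(tracks)) - 1L,
      FRAME = tracks$frame,
      POSITION_X = tracks$x,
      POSITION_Y = tracks$y,
      QUALITY = tracks$quality
    )
  } else {
    out <- tibble::tibble(
      TOTAL_TRACKS = c(n_tracks(tracks), rep(NA_integer_, nrow(tracks) - 1L)),
      FRAME = tracks$frame,
      POSITION_X = tracks$x,
      POSITION_Y = tracks$y
    )
  }
  readr::write_csv(out, path, na = "", eol = "\n")
  invisible(path)
}

#' Read a trajectory table (layout auto-detected by header)
#'
#' Extra columns beyond the ones named in [spots_tables] are ignored.
#' Row order does not matter for the `spots_in_tracks` layout; rows are
#' re-sorted by track and frame.
#'
#' @param path CSV path in either supported layout.
#' @return A tracks tibble.
#' @export
read_spots_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file does not exist: '%s'", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (all(c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y") %in% header)) {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    tracks <- tibble::tibble(
      track_id = as.integer(raw$TRACK_ID),
      frame = as.integer(raw$FRAME),
      x = as.numeric(raw$POSITION_X),
      y = as.numeric(raw$POSITION_Y),
      quality = if ("QUALITY" %in% header) as.numeric(raw$QUALITY) else NA_real_
    ) |>
      dplyr::arrange(.data$track_id, .data$frame)
    check_monotone_rows(tracks, path)
    return(tracks)
  }
  if (all(c("TOTAL_TRACKS", "FRAME", "POSITION_X", "POSITION_Y") %in% header)) {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    declared <- as.integer(raw$TOTAL_TRACKS[1])
    frame <- as.integer(raw$FRAME)
    # a new trajectory starts wherever the frame index fails to increase
    new_track <- c(TRUE, diff(frame) <= 0)
    tracks <- tibble::tibble(
      track_id = cumsum(new_track),
      frame = frame,
      x = as.numeric(raw$POSITION_X),
      y = as.numeric(raw$POSITION_Y),
      quality = NA_real_
    )
    if (!is.na(declared) && declared != n_tracks(tracks)) {
      abort(sprintf(
        "declared track count (%d) does not match contiguous blocks found (%d) in '%s'",
        declared, n_tracks(tracks), path))
    }
    check_monotone_rows(tracks, path)
    return(tracks)
  }
  abort(sprintf("unknown trajectory table header in '%s': %s",
                path, paste(header, collapse = ",")))
}

check_monotone_rows <- function(tracks, path) {
  keep <- tracks$track_id >= 0
  grp <- split(seq_len(nrow(tracks))[keep], tracks$track_id[keep])
  for (rows in grp) {
    f <- tracks$frame[rows]
    bad <- which(diff(f) <= 0)
    if (length(bad)) {
      abort(sprintf("non-monotone frames within a track at row %d of '%s'",
                    rows[bad[1] + 1L], path))
    }
  }
  invisible(tracks)
}
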