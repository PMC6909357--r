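#' Linking parameters for the two-pass LAP tracker
#'
#' Defaults are the workflow's printed tracker settings: 50 um maximum
#' linking distance, 50 um maximum gap-closing distance, maximum frame gap 8.
#' A frame gap of exactly 8 is allowed (up to 7 missing detections). Link
#' costs are squared Euclidean distances (um^2); birth/death alternatives
#' cost `alternative_cost_factor` times the maximum feasible cost, which
#' makes the assignment problem well-posed.
#'
#' @param linking_max_distance Maximum frame-to-frame link distance, um.
#' @param gap_closing_max_distance Maximum gap-closing distance, um.
#' @param gap_closing_max_frame_gap Maximum allowed frame difference for a
#'   gap link (inclusive).
#' @param alternative_cost_factor Birth/death cost multiplier (> 1).
#' @return A `linking_params` object.
#' @export
linking_params <- function(linking_max_distance = 50,
                           gap_closing_max_distance = 50,
                           gap_closing_max_frame_gap = 8,
                           alternative_cost_factor = 1.05) {
  if (!is_scalar_number(linking_max_distance) || linking_max_distance <= 0) {
    stop_field("linking_max_distance", "must be > 0 (um)")
  }
  if (!is_scalar_number(gap_closing_max_distance) ||
      gap_closing_max_distance <= 0) {
    stop_field("gap_closing_max_distance", "must be > 0 (um)")
  }
  if (!is_scalar_number(gap_closing_max_frame_gap) ||
      gap_closing_max_frame_gap < 1) {
    stop_field("gap_closing_max_frame_gap", "must be >= 1 frame")
  }
  if (!is_scalar_number(alternative_cost_factor) ||
      alternative_cost_factor <= 1) {
    stop_field("alternative_cost_factor", "must be > 1")
  }
  structure(list(linking_max_distance = linking_max_distance,
                 gap_closing_max_distance = gap_closing_max_distance,
                 gap_closing_max_frame_gap = as.integer(gap_closing_max_frame_gap),
                 alternative_cost_factor = alternative_cost_factor),
            class = "linking_params")
}

#' Frame-to-frame linking (first LAP pass)
#'
#' For each consecutive frame pair an optimal assignment links spots whose
#' distance does not exceed `linking_max_distance`; cost is squared distance.
#' Chains of links form segments; unlinked spots start or end segments.
#' No splitting or merging: every spot joins at most one segment.
#'
#' @param spots Spots tibble (`frame`, `x`, `y`, `quality`).
#' @param params A [linking_params()].
#' @return Segments tibble: the spots plus a `segment_id` column.
#' @export
link_frames <- function(spots, params = linking_params()) {
  stopifnot(is.data.frame(spots))
  if (nrow(spots) == 0L) {
    return(tibble::tibble(segment_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), quality = numeric(0)))
  }
  if (!"quality" %in% names(spots)) spots$quality <- NA_real_
  spots <- tibble::as_tibble(spots) |>
    dplyr::arrange(.data$frame, .data$y, .data$x) |>
    dplyr::mutate(.spot = dplyr::row_number())
  succ <- rep(NA_integer_, nrow(spots))
  by_frame <- split(spots, spots$frame)
  frames <- as.integer(names(by_frame))
  max2 <- params$linking_max_distance^2
  for (fi in seq_along(frames)) {
    if (!((frames[fi] + 1L) %in% frames)) next
    a <- by_frame[[fi]]
    b <- by_frame[[as.character(frames[fi] + 1L)]]
    cost <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
    cost[cost > max2] <- Inf
    sol <- solve_assignment(cost,
                            alternative_cost_factor = params$alternative_cost_factor)
    if (nrow(sol$matches)) {
      succ[a$.spot[sol$matches$source]] <- b$.spot[sol$matches$target]
    }
  }
  # walk chains from spots that are not anyone's successor
  is_start <- !(seq_len(nrow(spots)) %in% succ)
  seg_of <- rep(NA_integer_, nrow(spots))
  seg <- 0L
  for (s in which(is_start)) {
    seg <- seg + 1L
    i <- s
    while (!is.na(i)) {
      seg_of[i] <- seg
      i <- succ[i]
    }
  }
  spots$segment_id <- seg_of
  dplyr::select(spots, "segment_id", "frame", "x", "y", "quality") |>
    dplyr::arrange(.data$segment_id, .data$frame)
}

#' Gap closing (second LAP pass)
#'
#' One global assignment between segment ends and segment starts. A link is
#' feasible when `1 <= frame(start) - frame(end) <= gap_closing_max_frame_gap`
#' and the distance is within `gap_closing_max_distance`; cost is squared
#' distance (not scaled by the gap length). Each end joins at most one start,
#' so no splits or merges arise. Joined segments concatenate into tracks;
#' tracks keep their spot gaps (see [regularize_tracks()] for interpolation).
#' Segments with a single spot that remain unjoined are dropped (a track has
#' at least 2 spots).
#'
#' @param segments Segments tibble from [link_frames()].
#' @param params A [linking_params()].
#' @return Tracks tibble with consecutive `track_id` ordered by first frame.
#' @export
close_gaps <- function(segments, params = linking_params()) {
  stopifnot(is.data.frame(segments), "segment_id" %in% names(segments))
  if (nrow(segments) == 0L) {
    return(tibble::tibble(track_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), quality = numeric(0)))
  }
  segs <- segments |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      f_start = min(.data$frame), f_end = max(.data$frame),
      x_start = .data$x[which.min(.data$frame)],
      x_end = .data$x[which.max(.data$frame)],
      y_start = .data$y[which.min(.data$frame)],
      y_end = .data$y[which.max(.data$frame)],
      .groups = "drop") |>
    dplyr::arrange(.data$segment_id)
  ns <- nrow(segs)
  gap <- outer(segs$f_start, segs$f_end, `-`) |> t()  # [end i, start j]
  d2 <- (outer(segs$x_end, segs$x_start, `-`)^2 +
           outer(segs$y_end, segs$y_start, `-`)^2)
  feasible <- gap >= 1 & gap <= params$gap_closing_max_frame_gap &
    d2 <= params$gap_closing_max_distance^2
  cost <- ifelse(feasible, d2, Inf)
  succ <- rep(NA_integer_, ns)
  if (any(feasible)) {
    sol <- solve_assignment(cost,
                            alternative_cost_factor = params$alternative_cost_factor)
    if (nrow(sol$matches)) succ[sol$matches$source] <- sol$matches$target
  }
  # merge chains end -> start
  root <- rep(NA_integer_, ns)
  is_head <- !(seq_len(ns) %in% succ)
  for (hseg in which(is_head)) {
    i <- hseg
    while (!is.na(i)) {
      root[i] <- hseg
      i <- succ[i]
    }
  }
  out <- segments |>
    dplyr::mutate(.root = root[match(.data$segment_id, segs$segment_id)]) |>
    dplyr::group_by(.data$.root) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::ungroup()
  if (nrow(out) == 0L) {
    return(tibble::tibble(track_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), quality = numeric(0)))
  }
  # stable 1..K ids ordered by (first frame, first y, first x)
  ord <- out |>
    dplyr::group_by(.data$.root) |>
    dplyr::summarise(f0 = min(.data$frame),
                     y0 = .data$y[which.min(.data$frame)],
                     x0 = .data$x[which.min(.data$frame)], .groups = "drop") |>
    dplyr::arrange(.data$f0, .data$y0, .data$x0)
  out$track_id <- match(out$.root, ord$.root)
  dplyr::select(out, "track_id", "frame", "x", "y", "quality") |>
    dplyr::arrange(.data$track_id, .data$frame)
}

#' Link detections into tracks (both passes)
#'
#' Convenience wrapper: [link_frames()] then [close_gaps()].
#'
#' @inheritParams link_frames
#' @return Tracks tibble.
#' @export
link_tracks <- function(spots, params = linking_params()) {
  close_gaps(link_frames(spots, params), params)
}

#' Track filter
#'
#' @param min_duration Minimum duration in frames (`last - first + 1`),
#'   a number, `"auto"` (Otsu's threshold on the duration distribution) or
#'   `NULL` to disable.
#' @param min_quality Minimum mean spot quality; number, `"auto"` or `NULL`.
#' @return A `track_filter` object.
#' @export
track_filter <- function(min_duration = NULL, min_quality = NULL) {
  chk <- function(v, nm) {
    if (!is.null(v) && !identical(v, "auto") &&
        (!is_scalar_number(v) || v < 0)) {
      stop_field(nm, "must be NULL, \"auto\" or a number >= 0")
    }
  }
  chk(min_duration, "min_duration"); chk(min_quality, "min_quality")
  structure(list(min_duration = min_duration, min_quality = min_quality),
            class = "track_filter")
}

#' Filter tracks by duration and quality
#'
#' `"auto"` thresholds use [otsu_threshold()] on the per-track feature
#' distribution; tracks at or above the threshold are kept.
#'
#' @param tracks Tracks tibble.
#' @param filter A [track_filter()].
#' @return Filtered tracks tibble.
#' @export
filter_tracks <- function(tracks, filter = track_filter()) {
  stopifnot(inherits(filter, "track_filter"))
  if (is.null(filter$min_duration) && is.null(filter$min_quality)) {
    return(tracks)
  }
  feats <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(duration = max(.data$frame) - min(.data$frame) + 1,
                     mean_quality = mean(.data$quality), .groups = "drop")
  keep <- rep(TRUE, nrow(feats))
  if (!is.null(filter$min_duration)) {
    thr <- if (identical(filter$min_duration, "auto")) {
      otsu_threshold(feats$duration)
    } else filter$min_duration
    keep <- keep & feats$duration >= thr
  }
  if (!is.null(filter$min_quality)) {
    thr <- if (identical(filter$min_quality, "auto")) {
      otsu_threshold(feats$mean_quality)
    } else filter$min_quality
    keep <- keep & feats$mean_quality >= thr
  }
  dplyr::filter(tracks, .data$track_id %in% feats$track_id[keep])
}

#' Randomly subsample tracks
#'
#' Uniform sample without replacement of `min(n, total)` whole tracks,
#' deterministic for a given seed; the original row order is preserved
#' within the sample. Useful before [plot_at_origin()], which accepts at
#' most 256 trajectories.
#'
#' @param tracks Tracks tibble.
#' @param n Number of tracks to keep.
#' @param seed Integer seed.
#' @return Subsampled tracks tibble.
#' @export
subsample_tracks <- function(tracks, n, seed = 1L) {
  if (!is_scalar_number(n) || n < 1) stop_field("n", "must be >= 1")
  ids <- unique(tracks$track_id)
  if (n >= length(ids)) return(tracks)
  chosen <- withr::with_seed(seed, sample(ids, n))
  dplyr::filter(tracks, .data$track_id %in% chosen)
}
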