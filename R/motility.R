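#' Fill closed gaps by linear interpolation
#'
#' Gap-closed tracks can skip frames; the motility statistics assume a
#' uniform time base. Missing frames inside each track are filled by linear
#' interpolation between the flanking spots. Interpolated spots carry
#' `quality = 0` and `interpolated = TRUE`.
#'
#' @param tracks Tracks tibble.
#' @return Tracks tibble with complete frame runs per track and an
#'   `interpolated` column.
#' @export
regularize_tracks <- function(tracks) {
  tracks <- validate_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      full <- tibble::tibble(frame = seq(min(df$frame), max(df$frame)))
      if (nrow(full) == nrow(df)) {
        df$interpolated <- FALSE
        return(df)
      }
      out <- full
      out$x <- stats::approx(df$frame, df$x, xout = full$frame)$y
      out$y <- stats::approx(df$frame, df$y, xout = full$frame)$y
      out$interpolated <- !(full$frame %in% df$frame)
      out$quality <- ifelse(out$interpolated, 0,
                            df$quality[match(full$frame, df$frame)])
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select("track_id", "frame", "x", "y", "quality", "interpolated")
}

#' Per-track mean speed
#'
#' Speed = total path length divided by elapsed time: the sum of consecutive
#' step lengths (um) over the track duration (min). Tracks should be
#' regularized first so that the time base is uniform.
#'
#' @param tracks Tracks tibble (one or many tracks).
#' @param calibration A [calibration()] (supplies the frame interval).
#' @return Tibble `track_id`, `speed` (um/min).
#' @export
track_speed <- function(tracks, calibration) {
  cal <- as_calibration(calibration)
  validate_tracks(tracks) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      speed = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)) /
        ((max(.data$frame) - min(.data$frame)) * cal$frame_interval),
      .groups = "drop")
}

#' Per-track directionality ratio
#'
#' Net displacement over total path length: 1 for a straight path, toward 0
#' for confined or random motion. Tracks with zero path length have no
#' defined directionality (`NA`) and are excluded from summaries.
#'
#' @param tracks Tracks tibble.
#' @return Tibble `track_id`, `directionality` in `[0, 1]` (or `NA`).
#' @export
directionality_ratio <- function(tracks) {
  validate_tracks(tracks) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      directionality = {
        path <- sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2))
        disp <- sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                       (dplyr::last(.data$y) - dplyr::first(.data$y))^2)
        if (path > 0) disp / path else NA_real_
      },
      .groups = "drop")
}

#' Ensemble mean squared displacement
#'
#' Per track the MSD is time-averaged over all overlapping intervals:
#' `MSD_i(k dt) = mean_t |r(t + k) - r(t)|^2` for `k = 1 .. length - 1`.
#' The ensemble value at each lag is the mean over the tracks that reach that
#' lag, with its SEM and track count. Lags beyond half the longest track are
#' flagged `low_confidence` (few overlapping intervals, high variance).
#' A lag-0 row (MSD 0) anchors log-log displays.
#'
#' @param tracks Regularized tracks tibble.
#' @param calibration A [calibration()].
#' @return Tibble `lag` (frames), `lag_min`, `msd` (um^2), `sem`,
#'   `n_tracks`, `low_confidence`.
#' @export
msd <- function(tracks, calibration) {
  cal <- as_calibration(calibration)
  tracks <- validate_tracks(tracks)
  if (nrow(tracks) == 0L) abort("no tracks supplied")
  per_track <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$frame)
      n <- nrow(df)
      tibble::tibble(
        lag = seq_len(n - 1L),
        msd = vapply(seq_len(n - 1L), function(k) {
          dx <- df$x[(1 + k):n] - df$x[1:(n - k)]
          dy <- df$y[(1 + k):n] - df$y[1:(n - k)]
          mean(dx^2 + dy^2)
        }, numeric(1)))
    }) |>
    dplyr::ungroup()
  max_len <- max(per_track$lag) + 1L
  ens <- per_track |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(m = mean(.data$msd), sem = sem(.data$msd),
                     n_tracks = dplyr::n(), .groups = "drop")
  tibble::tibble(
    lag = c(0L, ens$lag),
    lag_min = c(0L, ens$lag) * cal$frame_interval,
    msd = c(0, ens$m),
    sem = c(0, ens$sem),
    n_tracks = c(max(ens$n_tracks), ens$n_tracks),
    low_confidence = c(0L, ens$lag) > (max_len - 1L) / 2
  )
}

#' Summarize the motility of a set of tracks
#'
#' Regularizes the tracks, computes per-track speed, directionality and
#' duration, and the ensemble MSD curve. Optionally writes the two CSV
#' summaries.
#'
#' @param tracks Tracks tibble.
#' @param calibration A [calibration()].
#' @param label Condition label carried through to outputs.
#' @param out_dir If given, writes `<label>_per_track.csv` and
#'   `<label>_msd.csv` there.
#' @return A `motility_summary`: list with `per_track`, `msd`, `label`,
#'   `calibration`. `tidy()` returns the per-track table, `glance()` a
#'   one-row mean +/- SEM summary, `autoplot()` the log-log MSD curve.
#' @export
summarize_motility <- function(tracks, calibration, label = "condition",
                               out_dir = NULL) {
  cal <- as_calibration(calibration)
  reg <- regularize_tracks(tracks)
  if (n_tracks(reg) < 1L) abort("no usable tracks")
  per_track <- reg |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(n_spots = dplyr::n(),
                     duration_min = (max(.data$frame) - min(.data$frame)) *
                       cal$frame_interval,
                     .groups = "drop") |>
    dplyr::left_join(track_speed(reg, cal), by = "track_id") |>
    dplyr::left_join(directionality_ratio(reg), by = "track_id") |>
    dplyr::rename(speed_um_per_min = "speed")
  out <- structure(list(per_track = per_track,
                        msd = msd(reg, cal),
                        label = label,
                        calibration = cal),
                   class = "motility_summary")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(per_track,
                     file.path(out_dir, paste0(label, "_per_track.csv")), eol = "\n")
    readr::write_csv(out$msd,
                     file.path(out_dir, paste0(label, "_msd.csv")), eol = "\n")
  }
  out
}

#' @export
print.motility_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<motility_summary> '%s': %d tracks\n  speed %.3g +/- %.2g um/min, directionality %.3g +/- %.2g\n",
    x$label, g$n_tracks, g$speed_mean, g$speed_sem,
    g$directionality_mean, g$directionality_sem))
  invisible(x)
}

#' @rdname summarize_motility
#' @param x A `motility_summary`.
#' @param ... Unused.
#' @method tidy motility_summary
#' @export
tidy.motility_summary <- function(x, ...) {
  dplyr::mutate(x$per_track, label = x$label)
}

#' @rdname summarize_motility
#' @method glance motility_summary
#' @export
glance.motility_summary <- function(x, ...) {
  pt <- x$per_track
  tibble::tibble(
    label = x$label,
    n_tracks = nrow(pt),
    speed_mean = mean(pt$speed_um_per_min, na.rm = TRUE),
    speed_sem = sem(pt$speed_um_per_min),
    directionality_mean = mean(pt$directionality, na.rm = TRUE),
    directionality_sem = sem(pt$directionality)
  )
}

#' Mann-Whitney comparison of two conditions
#'
#' Compares per-track speed or directionality between two conditions with a
#' two-sided Mann-Whitney U test (exact when both groups have fewer than 50
#' tracks and there are no ties; normal approximation with tie correction
#' otherwise), and reports group means +/- SEM.
#'
#' @param a,b `motility_summary` objects (or tibbles with the feature column).
#' @param feature `"speed"` or `"directionality"`.
#' @return A `condition_comparison`; `tidy()` gives a one-row tibble with the
#'   U statistic, p value and group summaries.
#' @export
compare_conditions <- function(a, b,
                               feature = c("directionality", "speed")) {
  feature <- match.arg(feature)
  col <- if (feature == "speed") "speed_um_per_min" else "directionality"
  get_vals <- function(s) {
    pt <- if (inherits(s, "motility_summary")) s$per_track else tibble::as_tibble(s)
    v <- pt[[col]] %||% pt[[feature]]
    if (is.null(v)) abort(sprintf("no '%s' column found", feature))
    v[is.finite(v)]
  }
  va <- get_vals(a); vb <- get_vals(b)
  if (length(va) < 3L || length(vb) < 3L) {
    abort("need at least 3 tracks per condition")
  }
  ties <- anyDuplicated(c(va, vb)) > 0L
  exact <- !ties && max(length(va), length(vb)) < 50L
  wt <- suppressWarnings(
    stats::wilcox.test(va, vb, alternative = "two.sided", exact = exact))
  structure(list(
    feature = feature,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    exact = exact,
    label_a = if (inherits(a, "motility_summary")) a$label else "a",
    label_b = if (inherits(b, "motility_summary")) b$label else "b",
    mean_a = mean(va), sem_a = sem(va), n_a = length(va),
    mean_b = mean(vb), sem_b = sem(vb), n_b = length(vb)),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<condition_comparison> %s: '%s' (%.3g +/- %.2g, n=%d) vs '%s' (%.3g +/- %.2g, n=%d)\n  Mann-Whitney U = %g, two-sided p = %.3g%s\n",
    x$feature, x$label_a, x$mean_a, x$sem_a, x$n_a,
    x$label_b, x$mean_b, x$sem_b, x$n_b,
    x$statistic, x$p_value, if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' @rdname compare_conditions
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @method tidy condition_comparison
#' @export
tidy.condition_comparison <- function(x, ...) {
  tibble::tibble(feature = x$feature, statistic = x$statistic,
                 p.value = x$p_value, exact = x$exact,
                 label_a = x$label_a, mean_a = x$mean_a, sem_a = x$sem_a,
                 n_a = x$n_a, label_b = x$label_b, mean_b = x$mean_b,
                 sem_b = x$sem_b, n_b = x$n_b)
}

#' @rdname compare_conditions
#' @method glance condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) tidy(x)
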