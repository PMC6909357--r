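#' Origin-aligned trajectory plot
#'
#' Translates every trajectory so its first spot sits at (0, 0) and
#' overplots them with equal axes — the standard "plot at origin" view of a
#' chemotaxis experiment (a biased population fans out toward +x). At most
#' 256 trajectories are accepted, mirroring the charting limit of the
#' quantification suite this view comes from; use [subsample_tracks()]
#' first, or set `override = TRUE`.
#'
#' @param tracks Tracks tibble.
#' @param max_series Trajectory limit (default 256).
#' @param override Allow more than `max_series` trajectories.
#' @param file Optional path; if given the figure is saved there.
#' @return A ggplot object.
#' @export
plot_at_origin <- function(tracks, max_series = 256L, override = FALSE,
                           file = NULL) {
  tracks <- validate_tracks(tracks)
  nt <- n_tracks(tracks)
  if (nt < 1L) abort("need at least one track")
  if (nt > max_series && !override) {
    abort(sprintf(
      "%d trajectories exceed the %d-series plotting limit; subsample first with subsample_tracks(tracks, n <= %d) or set override = TRUE",
      nt, max_series, max_series))
  }
  shifted <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(x0 = .data$x - dplyr::first(.data$x),
                  y0 = .data$y - dplyr::first(.data$y)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(shifted,
                       ggplot2::aes(.data$x0, .data$y0,
                                    group = .data$track_id,
                                    colour = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.7, linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = track_color(sort(unique(shifted$track_id)))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 5)
  p
}

#' @rdname summarize_motility
#' @param object A `motility_summary`.
#' @method autoplot motility_summary
#' @export
autoplot.motility_summary <- function(object, ...) {
  d <- dplyr::filter(object$msd, .data$lag > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$lag_min, .data$msd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$msd - .data$sem, .Machine$double.eps),
                                      ymax = .data$msd + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time interval (min)", y = "MSD (um^2)",
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Log-log MSD comparison of several conditions
#'
#' @param ... `motility_summary` objects.
#' @return A ggplot object.
#' @export
plot_msd <- function(...) {
  summaries <- list(...)
  d <- purrr::map(summaries, function(s) {
    dplyr::mutate(dplyr::filter(s$msd, .data$lag > 0), label = s$label)
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(.data$lag_min, .data$msd,
                                  colour = .data$label, fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$msd - .data$sem, .Machine$double.eps),
                                      ymax = .data$msd + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time interval (min)", y = "MSD (um^2)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
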