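#' Deterministic track colour
#'
#' Colour is a pure function of `track_id`: hues are spaced around the colour
#' wheel by the golden ratio so that hundreds of consecutive ids remain
#' visually distinct.
#'
#' @param track_id Integer vector of track ids.
#' @return Hex colour strings.
#' @export
track_color <- function(track_id) {
  golden <- (sqrt(5) - 1) / 2
  hue <- (as.numeric(track_id) * golden) %% 1
  grDevices::hsv(h = hue, s = 0.85, v = 1)
}

#' Render a track-overlay video
#'
#' Writes a multi-page RGB TIFF in which frame `t` shows the (contrast
#' normalized) image with each track's polyline drawn over all of its spots
#' with `frame <= t`, one colour per track. This mirrors the "capture
#' overlay" step used to visually validate automated tracks.
#'
#' @param stack A `celltrax_stack`.
#' @param tracks Tracks tibble; coordinates must lie within the stack bounds.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
render_overlay <- function(stack, tracks, path) {
  stopifnot(inherits(stack, "celltrax_stack"))
  cal <- attr(stack, "calibration")
  d <- dim(stack)
  h <- d[1]; w <- d[2]; nt <- d[3]
  lo <- min(stack); hi <- max(stack)
  span <- if (hi > lo) hi - lo else 1
  have_tracks <- !is.null(tracks) && nrow(tracks) > 0L
  if (have_tracks) {
    tracks <- validate_tracks(tracks, require_two = FALSE)
    col_px <- tracks$x / cal$pixel_size + 1
    row_px <- tracks$y / cal$pixel_size + 1
    if (any(col_px < 1 - 1e-9 | col_px > w + 1e-9 |
            row_px < 1 - 1e-9 | row_px > h + 1e-9)) {
      abort("track coordinates fall outside the stack bounds")
    }
    tracks$.row <- pmin(pmax(row_px, 1), h)
    tracks$.col <- pmin(pmax(col_px, 1), w)
    by_track <- split(tracks, tracks$track_id)
    rgb_track <- grDevices::col2rgb(track_color(as.integer(names(by_track)))) / 255
  }
  pages <- vector("list", nt)
  for (t in seq_len(nt)) {
    g <- (get_frame(stack, t) - lo) / span
    page <- array(g, dim = c(h, w, 3))
    if (have_tracks) {
      for (k in seq_along(by_track)) {
        tk <- by_track[[k]]
        vis <- tk$frame <= (t - 1L)
        if (!any(vis)) next
        pts <- polyline_pixels(tk$.row[vis], tk$.col[vis], h, w)
        page[cbind(pts$row, pts$col, 1L)] <- rgb_track[1, k]
        page[cbind(pts$row, pts$col, 2L)] <- rgb_track[2, k]
        page[cbind(pts$row, pts$col, 3L)] <- rgb_track[3, k]
      }
    }
    pages[[t]] <- page
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

# rasterize a polyline through (row, col) vertices by dense sampling
polyline_pixels <- function(rows, cols, h, w) {
  if (length(rows) == 1L) {
    return(list(row = round(rows), col = round(cols)))
  }
  out_r <- integer(0); out_c <- integer(0)
  for (i in seq_len(length(rows) - 1L)) {
    n <- max(2L, ceiling(max(abs(rows[i + 1] - rows[i]),
                             abs(cols[i + 1] - cols[i]))) * 2L)
    s <- seq(0, 1, length.out = n)
    out_r <- c(out_r, round(rows[i] + s * (rows[i + 1] - rows[i])))
    out_c <- c(out_c, round(cols[i] + s * (cols[i + 1] - cols[i])))
  }
  keep <- out_r >= 1 & out_r <= h & out_c >= 1 & out_c <= w
  list(row = out_r[keep], col = out_c[keep])
}
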