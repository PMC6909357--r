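#' Spatial and temporal calibration of a time-lapse stack
#'
#' Bundles the pixel size and frame interval that convert pixel/frame indices
#' into physical units. All trajectory coordinates in this package are
#' calibrated: `x = (column - 1) * pixel_size`, `y = (row - 1) * pixel_size`,
#' with the origin at the centre of the top-left pixel and `y` increasing
#' downward; frames are 0-based.
#'
#' @param pixel_size Length of one pixel side, in micrometres per pixel.
#' @param frame_interval Time between consecutive frames, in minutes
#'   (e.g. 2 min for dendritic cells, 15 min for MDA-MB-231 cells).
#' @param length_unit Label for the length unit (default `"um"`).
#' @return A `celltrax_calibration` object (a named list).
#' @examples
#' calibration(pixel_size = 2, frame_interval = 2)
#' @export
calibration <- function(pixel_size, frame_interval, length_unit = "um") {
  if (!is_scalar_number(pixel_size) || pixel_size <= 0) {
    stop_field("pixel_size", "must be a single positive number (um/px)")
  }
  if (!is_scalar_number(frame_interval) || frame_interval <= 0) {
    stop_field("frame_interval", "must be a single positive number (min/frame)")
  }
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         length_unit = length_unit),
    class = "celltrax_calibration"
  )
}

as_calibration <- function(x) {
  if (inherits(x, "celltrax_calibration")) return(x)
  if (inherits(x, "celltrax_stack")) return(attr(x, "calibration"))
  if (is.list(x) && all(c("pixel_size", "frame_interval") %in% names(x))) {
    return(calibration(x$pixel_size, x$frame_interval,
                       x$length_unit %||% "um"))
  }
  abort("expected a calibration object (see `calibration()`) or an image stack")
}

#' Construct a calibrated image stack
#'
#' An image stack is a `H x W x T` numeric array of pixel intensities with an
#' attached [calibration()]. Intensities are arbitrary units (float
#' internally, whatever the source bit depth).
#'
#' @param frames A `H x W x T` array, or a list of `T` equally sized matrices.
#' @param calibration A [calibration()] object.
#' @return A `celltrax_stack` object.
#' @export
image_stack <- function(frames, calibration) {
  cal <- as_calibration(calibration)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L || length(dims[[1]]) != 2L) {
      abort("all frames must be matrices of identical size")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be an H x W x T array or list of matrices")
  }
  d <- dim(frames)
  if (d[3] < 2L) abort("an image stack needs at least 2 frames")
  if (d[1] < 16L || d[2] < 16L) abort("frames must be at least 16 x 16 pixels")
  if (!all(is.finite(frames))) abort("all pixel intensities must be finite")
  structure(frames, calibration = cal, class = "celltrax_stack")
}

#' @export
print.celltrax_stack <- function(x, ...) {
  d <- dim(x)
  cal <- attr(x, "calibration")
  cat(sprintf(
    "<celltrax_stack> %d frames of %d x %d px (%g %s/px, %g min/frame)\n",
    d[3], d[1], d[2], cal$pixel_size, cal$length_unit, cal$frame_interval))
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `celltrax_stack`.
#' @return Integer frame count `T`.
#' @export
n_frames <- function(stack) dim(stack)[3]

get_frame <- function(stack, t) stack[, , t, drop = TRUE]

# Fixed storage convention: TIFF pages hold value / 65535 as 32-bit float,
# so any intensity in [0, 65535] survives a round trip to float32 precision
# (~6e-8 relative). 8/16-bit integer TIFFs from other tools are read back on
# their native integer scale.
.tiff_scale <- 65535

#' Read a multi-page grayscale TIFF as a calibrated stack
#'
#' Calibration is supplied by the caller, not parsed from TIFF tags: the
#' imaging workflow this package mirrors assigns pixel size and frame interval
#' manually, and a config value must win over possibly stale tags.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param calibration A [calibration()] object.
#' @return A [image_stack()].
#' @export
read_stack <- function(path, calibration) {
  cal <- as_calibration(calibration)
  if (!file.exists(path)) {
    abort(sprintf("stack file does not exist: '%s'", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    abort(sprintf("'%s' has %d page(s); a time-lapse stack needs at least 2",
                  path, length(pages)))
  }
  bad <- which(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))
  if (length(bad)) {
    abort(sprintf("page %d of '%s' is not grayscale (multi-channel data)",
                  bad[1], path))
  }
  scale <- vapply(pages, function(p) {
    bps <- attr(p, "bits.per.sample") %||% 32L
    if (identical(bps, 8L)) 255 else .tiff_scale
  }, numeric(1))
  frames <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    attributes(m) <- list(dim = dim(m))
    m * scale[i]
  })
  image_stack(frames, cal)
}

#' Write a stack as a multi-page 32-bit float TIFF
#'
#' Intensities must lie in `[0, 65535]` (the storage scale); they are written
#' as `value / 65535` float32 pages and recovered by [read_stack()].
#'
#' @param stack A `celltrax_stack`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "celltrax_stack"))
  if (min(stack) < 0 || max(stack) > .tiff_scale) {
    abort(sprintf(
      "stack intensities must lie in [0, %d] for TIFF storage; rescale first",
      .tiff_scale))
  }
  frames <- lapply(seq_len(n_frames(stack)),
                   function(t) get_frame(stack, t) / .tiff_scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
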