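#' Detection parameters
#'
#' Settings of the Laplacian-of-Gaussian (LoG) spot detector. The defaults
#' are the workflow's dendritic-cell settings: 30 um blob diameter (use 40 um
#' for MDA-MB-231 cells), quality threshold 25 (meaningful on `[0, 255]`
#' contrast-normalized frames; it scales with intensity, so treat it as a
#' calibration input for other scales), no median filter, sub-pixel
#' localization on.
#'
#' @param blob_diameter Estimated cell diameter, um. The filter scale is
#'   `sigma = blob_diameter / (2 * sqrt(2))`: a scale-normalized LoG responds
#'   maximally to a disc of radius `sigma * sqrt(2)`.
#' @param quality_threshold Minimum detector response to keep a spot.
#' @param subpixel Refine peak positions by parabolic interpolation.
#' @param median_filter Apply a 3x3 median filter before the LoG.
#' @param auto_quality Replace `quality_threshold` by Otsu's threshold on the
#'   frame's local-maxima qualities (the "auto" initial thresholding rule).
#' @return A `detection_params` object.
#' @export
detection_params <- function(blob_diameter = 30,
                             quality_threshold = 25,
                             subpixel = TRUE,
                             median_filter = FALSE,
                             auto_quality = FALSE) {
  if (!is_scalar_number(blob_diameter) || blob_diameter <= 0) {
    stop_field("blob_diameter", "must be > 0 (um)")
  }
  if (!is_scalar_number(quality_threshold) || quality_threshold < 0) {
    stop_field("quality_threshold", "must be >= 0")
  }
  structure(list(blob_diameter = blob_diameter,
                 quality_threshold = quality_threshold,
                 subpixel = isTRUE(subpixel),
                 median_filter = isTRUE(median_filter),
                 auto_quality = isTRUE(auto_quality)),
            class = "detection_params")
}

log_sigma_px <- function(blob_diameter, pixel_size) {
  (blob_diameter / (2 * sqrt(2))) / pixel_size
}

# Sampled scale-normalized LoG kernel: -sigma^2 * Laplacian(Gaussian).
# DC-corrected so a constant image gives exactly zero response.
log_kernel <- function(sigma_px, radius = ceiling(4 * sigma_px)) {
  ax <- (-radius):radius
  r2 <- outer(ax^2, ax^2, `+`)
  g <- exp(-r2 / (2 * sigma_px^2)) / (2 * pi * sigma_px^2)
  k <- (2 - r2 / sigma_px^2) * g
  k - mean(k)
}

#' Scale-normalized LoG response of one frame
#'
#' Bright blobs of the matched diameter yield positive response peaks.
#' Borders are handled by reflection padding.
#'
#' @param frame Numeric matrix.
#' @param blob_diameter Blob diameter in um.
#' @param calibration A [calibration()] (supplies the pixel size).
#' @return Response matrix of the same size.
#' @export
log_response <- function(frame, blob_diameter, calibration) {
  cal <- as_calibration(calibration)
  sigma <- log_sigma_px(blob_diameter, cal$pixel_size)
  if (sigma < 0.8) {
    abort(sprintf(
      "LoG scale %.2f px is below 0.8 px and unresolvable; increase blob_diameter",
      sigma))
  }
  if (!all(is.finite(frame))) abort("frame contains non-finite values")
  conv2_reflect(frame, log_kernel(sigma))
}

#' Detect spots in every frame of a stack
#'
#' Per frame: optional 3x3 median filter; LoG response; strict 8-neighbour
#' local maxima with response at or above the quality threshold; maxima
#' closer than `blob_diameter / 2` suppressed keeping the higher quality
#' (ties break in raster order); optional sub-pixel refinement. Quality is
#' the response at the integer maximum.
#'
#' @param stack A (preprocessed) `celltrax_stack`.
#' @param params A [detection_params()].
#' @return Spots tibble: `frame` (0-based), `x`, `y` (um), `quality`.
#'   Export unlinked detections with [write_spots_table()] after adding
#'   `track_id = -1`.
#' @export
detect_spots <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "celltrax_stack"))
  cal <- attr(stack, "calibration")
  res <- purrr::map(seq_len(n_frames(stack)), function(t) {
    fr <- get_frame(stack, t)
    if (params$median_filter) fr <- median3x3(fr)
    resp <- log_response(fr, params$blob_diameter, cal)
    detect_frame(resp, t - 1L, params, cal)
  })
  dplyr::bind_rows(res)
}

detect_frame <- function(resp, frame0, params, cal) {
  peaks <- local_maxima(resp)
  if (nrow(peaks) == 0L) return(empty_spots())
  q <- resp[cbind(peaks$row, peaks$col)]
  thr <- params$quality_threshold
  if (params$auto_quality) thr <- otsu_threshold(q)
  keep <- q >= thr
  peaks <- peaks[keep, , drop = FALSE]; q <- q[keep]
  if (nrow(peaks) == 0L) return(empty_spots())
  # non-maximum suppression within blob_diameter / 2 (um)
  ord <- order(-q, peaks$row, peaks$col)
  px <- cal$pixel_size
  min_d2 <- (params$blob_diameter / 2)^2
  acc_r <- numeric(0); acc_c <- numeric(0); acc <- integer(0)
  for (i in ord) {
    r <- peaks$row[i]; c <- peaks$col[i]
    if (length(acc) == 0L ||
        min((acc_r - r)^2 + (acc_c - c)^2) * px^2 >= min_d2) {
      acc <- c(acc, i); acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
    }
  }
  acc <- sort(acc)  # raster order output
  rows <- peaks$row[acc]; cols <- peaks$col[acc]
  xy <- purrr::map(seq_along(acc), function(j) {
    if (params$subpixel) {
      refine_subpixel(resp, rows[j], cols[j], px)
    } else {
      c(x = (cols[j] - 1) * px, y = (rows[j] - 1) * px)
    }
  })
  tibble::tibble(
    frame = frame0,
    x = vapply(xy, `[[`, numeric(1), "x"),
    y = vapply(xy, `[[`, numeric(1), "y"),
    quality = q[acc]
  )
}

empty_spots <- function() {
  tibble::tibble(frame = integer(0), x = numeric(0), y = numeric(0),
                 quality = numeric(0))
}

# strict 8-neighbourhood local maxima (border pixels compared against
# existing neighbours only)
local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- m
  ok <- matrix(TRUE, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      ok <- ok & (m > p[(2:(h + 1)) + dr, (2:(w + 1)) + dc])
    }
  }
  idx <- which(ok, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2])
}

median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- pad_reflect(m, 1L, 1L)
  stackv <- vapply(1:9, function(k) {
    dr <- (k - 1L) %/% 3L; dc <- (k - 1L) %% 3L
    as.vector(p[(1:h) + dr, (1:w) + dc])
  }, numeric(h * w))
  matrix(apply(stackv, 1L, stats::median), h, w)
}

#' Sub-pixel peak refinement by parabolic interpolation
#'
#' Per axis a parabola is fitted through the three response values centred on
#' the integer peak; the vertex offset
#' `(R_minus - R_plus) / (2 * (R_minus - 2 R_0 + R_plus))` is clamped to
#' `[-0.5, 0.5]` px. Degenerate (non-concave) curvature or a border peak
#' yields offset 0.
#'
#' @param response LoG response matrix.
#' @param row,col Integer pixel coordinates of a strict local maximum.
#' @param pixel_size um per pixel.
#' @return Named vector `c(x =, y =)` in um.
#' @export
refine_subpixel <- function(response, row, col, pixel_size) {
  off <- function(rm, r0, rp) {
    den <- rm - 2 * r0 + rp
    if (den >= 0) return(0)
    max(-0.5, min(0.5, (rm - rp) / (2 * den)))
  }
  h <- nrow(response); w <- ncol(response)
  dx <- if (col > 1L && col < w) {
    off(response[row, col - 1L], response[row, col], response[row, col + 1L])
  } else 0
  dy <- if (row > 1L && row < h) {
    off(response[row - 1L, col], response[row, col], response[row + 1L, col])
  } else 0
  c(x = (col - 1 + dx) * pixel_size, y = (row - 1 + dy) * pixel_size)
}
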