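#' Preprocessing parameters
#'
#' Controls background subtraction and saturation-bounded contrast
#' normalization for phase-contrast stacks. The defaults mirror the
#' processing applied before detection in the chemotaxis workflow:
#' 0.1% saturated pixels (split equally between the low and high tail),
#' per-frame histograms, negatives clipped, output on a `[0, 255]` scale so
#' the default detector threshold keeps its meaning.
#'
#' @param saturated_fraction Fraction of pixels allowed to saturate
#'   (default 0.001 = 0.1%); half at each tail.
#' @param per_frame_histogram Compute cut values per frame (`TRUE`, the
#'   "per-slice histogram" behaviour) or from the pooled stack histogram.
#' @param clip_negative Floor subtraction results at 0, mirroring
#'   unsigned-integer image arithmetic. Set `FALSE` to preserve sign (phase
#'   contrast cells can be darker than background).
#' @param output_range Two-element target intensity interval.
#' @return A `preprocess_params` object.
#' @export
preprocess_params <- function(saturated_fraction = 0.001,
                              per_frame_histogram = TRUE,
                              clip_negative = TRUE,
                              output_range = c(0, 255)) {
  if (!is_scalar_number(saturated_fraction) ||
      saturated_fraction < 0 || saturated_fraction >= 0.5) {
    stop_field("saturated_fraction", "must lie in [0, 0.5)")
  }
  if (length(output_range) != 2L || output_range[2] <= output_range[1]) {
    stop_field("output_range", "must be an increasing interval")
  }
  structure(list(saturated_fraction = saturated_fraction,
                 per_frame_histogram = isTRUE(per_frame_histogram),
                 clip_negative = isTRUE(clip_negative),
                 output_range = as.numeric(output_range)),
            class = "preprocess_params")
}

#' Average-intensity time projection
#'
#' @param stack A `celltrax_stack`.
#' @return A matrix: the pixel-wise arithmetic mean over all frames.
#' @export
average_projection <- function(stack) {
  stopifnot(inherits(stack, "celltrax_stack"))
  d <- dim(stack)
  matrix(rowMeans(matrix(unclass(stack), d[1] * d[2], d[3])), d[1], d[2])
}

#' Subtract a background projection from every frame
#'
#' @param stack A `celltrax_stack`.
#' @param projection Background image, typically [average_projection()].
#' @param params A [preprocess_params()]; `clip_negative` floors results at 0.
#' @return A `celltrax_stack` of background-subtracted frames.
#' @export
subtract_background <- function(stack, projection,
                                params = preprocess_params()) {
  stopifnot(inherits(stack, "celltrax_stack"))
  d <- dim(stack)
  if (!identical(dim(projection), d[1:2])) {
    abort("projection shape does not match the stack frames")
  }
  out <- unclass(stack) - as.vector(projection)  # recycles over frames
  if (params$clip_negative) out <- pmax(out, 0)
  structure(out, calibration = attr(stack, "calibration"),
            class = "celltrax_stack")
}

#' Saturation-bounded contrast normalization
#'
#' Per frame (or for the pooled stack when `per_frame_histogram = FALSE`),
#' cut values are the order statistics that leave `saturated_fraction/2` of
#' the pixels strictly below/above; `[low, high]` is mapped linearly onto
#' `output_range` and clamped. A constant frame maps to all zeros.
#'
#' @inheritParams subtract_background
#' @return A `celltrax_stack` with intensities in `output_range`.
#' @export
enhance_contrast <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "celltrax_stack"))
  arr <- unclass(stack)
  if (params$per_frame_histogram) {
    for (t in seq_len(dim(arr)[3])) {
      arr[, , t] <- normalize_frame(arr[, , t], params)
    }
  } else {
    cuts <- saturation_cuts(as.vector(arr), params$saturated_fraction)
    for (t in seq_len(dim(arr)[3])) {
      arr[, , t] <- apply_cuts(arr[, , t], cuts, params$output_range)
    }
  }
  structure(arr, calibration = attr(stack, "calibration"),
            class = "celltrax_stack")
}

saturation_cuts <- function(v, saturated_fraction) {
  s <- sort(v)
  n <- length(s)
  k <- floor(n * saturated_fraction / 2)
  c(low = s[k + 1L], high = s[n - k])
}

apply_cuts <- function(frame, cuts, output_range) {
  low <- cuts[["low"]]; high <- cuts[["high"]]
  if (high <= low) return(frame * 0)
  scaled <- (frame - low) / (high - low)
  output_range[1] + pmin(pmax(scaled, 0), 1) * diff(output_range)
}

normalize_frame <- function(frame, params) {
  apply_cuts(frame, saturation_cuts(as.vector(frame), params$saturated_fraction),
             params$output_range)
}

#' Full preprocessing: projection, subtraction, contrast normalization
#'
#' @inheritParams subtract_background
#' @return A processed `celltrax_stack` ready for detection.
#' @export
preprocess_stack <- function(stack, params = preprocess_params()) {
  proj <- average_projection(stack)
  enhance_contrast(subtract_background(stack, proj, params), params)
}

#' Batch-preprocess a folder of TIFF stacks
#'
#' Mirrors the three-folder macro flow: every TIFF in `input_dir` yields its
#' average projection in `projection_dir` and its processed stack in
#' `output_dir`.
#'
#' @param input_dir Directory containing multi-page TIFF stacks.
#' @param projection_dir,output_dir Output directories (created if missing).
#' @param calibration A [calibration()] applied to every stack.
#' @param params A [preprocess_params()].
#' @return Tibble with one row per processed stack, invisibly.
#' @export
preprocess_dir <- function(input_dir, projection_dir, output_dir,
                           calibration, params = preprocess_params()) {
  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) abort(sprintf("no TIFF files found in '%s'", input_dir))
  dir.create(projection_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- purrr::map(files, function(f) {
    stack <- read_stack(f, calibration)
    proj <- average_projection(stack)
    base <- sub("\\.[^.]*$", "", basename(f))
    ppath <- file.path(projection_dir, paste0(base, "_projection.tif"))
    tiff::writeTIFF(proj / 65535, ppath, bits.per.sample = 32L, reduce = FALSE)
    processed <- enhance_contrast(subtract_background(stack, proj, params), params)
    opath <- file.path(output_dir, paste0(base, "_processed.tif"))
    write_stack(processed, opath)
    tibble::tibble(input = f, projection = ppath, processed = opath)
  })
  invisible(dplyr::bind_rows(res))
}
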