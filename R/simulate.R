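#' Configuration for synthetic migrating-cell videos
#'
#' Parameterizes a biased persistent random walk rendered as bright
#' Gaussian blobs over an optional static collagen-like texture, emulating a
#' background-subtracted phase-contrast chemotaxis video. Defaults describe a
#' dendritic-cell-like acquisition: 2 min frame interval, 4 h of imaging
#' (121 frames), 30 um cells, with plausible (not measured) speeds.
#'
#' @param n_cells Number of cells.
#' @param image_size `c(H, W)` in pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval Minutes per frame.
#' @param speed_mean,speed_sd Instantaneous speed distribution, um/min
#'   (per-step speeds are `max(0, Normal(speed_mean, speed_sd))`).
#' @param persistence_sd Turning-angle spread, radians per step: the heading
#'   performs a wrapped Gaussian walk with this standard deviation. Small
#'   values give persistent motion.
#' @param bias_weight Chemotactic bias in `[0, 1]`: step directions are
#'   `normalize((1 - bias) * heading + bias * (+x))`. 0 = random migration,
#'   1 = fully directed along the gradient (+x).
#' @param blob_diameter Apparent cell diameter, um (cells are rendered as
#'   isotropic Gaussian bumps with sd `blob_diameter / 4`).
#' @param blob_amplitude Peak intensity of a rendered cell.
#' @param background_texture_amplitude SD of the static smoothed-noise
#'   background texture (0 = processed-like, already subtracted).
#' @param noise_sd Per-pixel, per-frame Gaussian noise SD.
#' @param n_frames Number of frames (>= 2).
#' @param vanish_probability Per cell and frame probability of not being
#'   rendered; creates detection gaps that exercise gap closing.
#' @param min_separation Minimum initial distance between cells, um
#'   (rejection-sampled placement; 0 = plain uniform placement).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_cells = 30,
                              image_size = c(256, 256),
                              pixel_size = 2,
                              frame_interval = 2,
                              speed_mean = 5,
                              speed_sd = 2,
                              persistence_sd = 0.35,
                              bias_weight = 0,
                              blob_diameter = 30,
                              blob_amplitude = 150,
                              background_texture_amplitude = 0,
                              noise_sd = 30,
                              n_frames = 121,
                              vanish_probability = 0,
                              min_separation = 0,
                              seed = 1) {
  if (!is_scalar_number(n_cells) || n_cells < 1) {
    stop_field("n_cells", "must be >= 1")
  }
  if (length(image_size) != 2L || any(image_size < 16)) {
    stop_field("image_size", "must be c(H, W) with both >= 16")
  }
  if (!is_scalar_number(speed_mean) || speed_mean <= 0) {
    stop_field("speed_mean", "must be > 0 (um/min)")
  }
  if (!is_scalar_number(speed_sd) || speed_sd < 0) {
    stop_field("speed_sd", "must be >= 0")
  }
  if (!is_scalar_number(persistence_sd) || persistence_sd < 0) {
    stop_field("persistence_sd", "must be >= 0 (radians)")
  }
  if (!is_scalar_number(bias_weight) || bias_weight < 0 || bias_weight > 1) {
    stop_field("bias_weight", "must lie in [0, 1]")
  }
  if (!is_scalar_number(blob_diameter) || blob_diameter <= 0) {
    stop_field("blob_diameter", "must be > 0 (um)")
  }
  if (!is_scalar_number(n_frames) || n_frames < 2) {
    stop_field("n_frames", "must be >= 2")
  }
  if (!is_scalar_number(vanish_probability) ||
      vanish_probability < 0 || vanish_probability >= 1) {
    stop_field("vanish_probability", "must lie in [0, 1)")
  }
  if (!is_scalar_number(min_separation) || min_separation < 0) {
    stop_field("min_separation", "must be >= 0 (um)")
  }
  if (!is_scalar_number(seed) || seed != round(seed) || abs(seed) > 2^30) {
    stop_field("seed", "must be an integer with |seed| <= 2^30")
  }
  structure(
    list(n_cells = as.integer(n_cells),
         image_size = as.integer(image_size),
         pixel_size = pixel_size,
         frame_interval = frame_interval,
         speed_mean = speed_mean, speed_sd = speed_sd,
         persistence_sd = persistence_sd, bias_weight = bias_weight,
         blob_diameter = blob_diameter, blob_amplitude = blob_amplitude,
         background_texture_amplitude = background_texture_amplitude,
         noise_sd = noise_sd, n_frames = as.integer(n_frames),
         vanish_probability = vanish_probability,
         min_separation = min_separation,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

sim_calibration <- function(config) {
  calibration(config$pixel_size, config$frame_interval)
}

#' Simulate ground-truth trajectories
#'
#' Each cell starts uniformly in the field interior with a uniform heading.
#' Per step the heading receives a wrapped Gaussian increment
#' (`persistence_sd`), the step direction mixes heading and gradient
#' direction by `bias_weight`, the step length is
#' `max(0, Normal(speed_mean, speed_sd)) * frame_interval`, and positions are
#' reflected at the field boundaries.
#'
#' @param config A [simulation_config()].
#' @return A `ground_truth` object: list with `tracks` (tibble of true
#'   positions, one row per cell and frame, quality 1) and `rendered`
#'   (tibble flagging which (cell, frame) pairs are rendered).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  px <- config$pixel_size
  xmax <- (w - 1) * px; ymax <- (h - 1) * px
  n <- config$n_cells; nf <- config$n_frames
  dt <- config$frame_interval
  b <- config$bias_weight

  withr::with_seed(config$seed, {
    pos <- sample_initial_positions(n, xmax, ymax, config$min_separation)
    theta <- runif(n, 0, 2 * pi)
    xs <- matrix(NA_real_, nf, n); ys <- matrix(NA_real_, nf, n)
    xs[1, ] <- pos$x; ys[1, ] <- pos$y
    for (t in 2:nf) {
      theta <- (theta + rnorm(n, 0, config$persistence_sd)) %% (2 * pi)
      ux <- (1 - b) * cos(theta) + b
      uy <- (1 - b) * sin(theta)
      nrm <- sqrt(ux^2 + uy^2)
      deg <- nrm < 1e-12   # bias exactly cancels the heading
      ux <- ifelse(deg, cos(theta), ux / pmax(nrm, 1e-12))
      uy <- ifelse(deg, sin(theta), uy / pmax(nrm, 1e-12))
      step <- pmax(0, rnorm(n, config$speed_mean, config$speed_sd)) * dt
      xs[t, ] <- fold_reflect(xs[t - 1, ] + ux * step, xmax)
      ys[t, ] <- fold_reflect(ys[t - 1, ] + uy * step, ymax)
    }
    rendered <- matrix(runif(nf * n) >= config$vanish_probability, nf, n)
  })

  tracks <- tibble::tibble(
    track_id = rep(seq_len(n), each = nf),
    frame = rep(0:(nf - 1), times = n),
    x = as.vector(xs), y = as.vector(ys),
    quality = 1
  )
  structure(
    list(tracks = tracks,
         rendered = tibble::tibble(
           track_id = rep(seq_len(n), each = nf),
           frame = rep(0:(nf - 1), times = n),
           rendered = as.vector(rendered)),
         config = config),
    class = "ground_truth"
  )
}

# dart-throwing with whole-pattern restarts: sequential rejection alone can
# deadlock near the packing limit
sample_initial_positions <- function(n, xmax, ymax, min_separation) {
  lo_x <- 0.1 * xmax; hi_x <- 0.9 * xmax
  lo_y <- 0.1 * ymax; hi_y <- 0.9 * ymax
  for (restart in 1:500) {
    x <- numeric(0); y <- numeric(0)
    tries <- 0L
    while (length(x) < n && tries < 400L * n) {
      cx <- runif(1, lo_x, hi_x); cy <- runif(1, lo_y, hi_y)
      ok <- length(x) == 0L || min_separation <= 0 ||
        min(sqrt((x - cx)^2 + (y - cy)^2)) >= min_separation
      if (ok) { x <- c(x, cx); y <- c(y, cy) }
      tries <- tries + 1L
    }
    if (length(x) == n) return(list(x = x, y = y))
  }
  abort("could not place cells with the requested min_separation")
}

#' Render a ground truth as an image stack
#'
#' Frame `t` = static background texture (seeded smoothed noise, identical in
#' every frame) + one isotropic Gaussian bump of amplitude `blob_amplitude`
#' and sd `blob_diameter/4` per rendered cell + independent
#' `Normal(0, noise_sd)` pixel noise, clipped at 0. The render noise stream
#' is seeded with `config$seed + 1` so tracks and pixels are independently
#' reproducible.
#'
#' @param truth A `ground_truth` from [simulate_tracks()].
#' @param config The same [simulation_config()].
#' @return A `celltrax_stack`.
#' @export
render_video <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  px <- config$pixel_size
  if (config$blob_diameter < 2 * px) {
    abort("blob_diameter below 2 pixels cannot be resolved; decrease pixel_size")
  }
  h <- config$image_size[1]; w <- config$image_size[2]
  nf <- config$n_frames
  sd_px <- (config$blob_diameter / 4) / px
  win <- ceiling(4 * sd_px)
  rend <- matrix(truth$rendered$rendered, nf, config$n_cells)
  xs <- matrix(truth$tracks$x, nf, config$n_cells)
  ys <- matrix(truth$tracks$y, nf, config$n_cells)

  frames <- withr::with_seed(config$seed + 1L, {
    texture <- if (config$background_texture_amplitude > 0) {
      tx <- conv2_reflect(matrix(rnorm(h * w), h, w), gaussian_kernel_2d(4))
      tx * (config$background_texture_amplitude / stats::sd(tx))
    } else {
      matrix(0, h, w)
    }
    lapply(seq_len(nf), function(t) {
      fr <- texture
      for (i in seq_len(config$n_cells)) {
        if (!rend[t, i]) next
        fr <- add_gaussian_bump(fr, row = ys[t, i] / px + 1,
                                col = xs[t, i] / px + 1,
                                amplitude = config$blob_amplitude,
                                sd_px = sd_px, win = win)
      }
      if (config$noise_sd > 0) fr <- fr + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
      pmax(fr, 0)
    })
  })
  image_stack(frames, sim_calibration(config))
}

add_gaussian_bump <- function(frame, row, col, amplitude, sd_px, win) {
  h <- nrow(frame); w <- ncol(frame)
  r0 <- max(1L, floor(row - win)); r1 <- min(h, ceiling(row + win))
  c0 <- max(1L, floor(col - win)); c1 <- min(w, ceiling(col + win))
  if (r0 > r1 || c0 > c1) return(frame)
  rr <- r0:r1; cc <- c0:c1
  bump <- amplitude * exp(-outer((rr - row)^2, (cc - col)^2, `+`) / (2 * sd_px^2))
  frame[rr, cc] <- frame[rr, cc] + bump
  frame
}

#' Write a complete synthetic fixture to disk
#'
#' Writes `stack.tif` (the rendered video), `truth.csv` (ground-truth tracks
#' in the diper layout) and `config.yaml`. Regeneration with the same seed is
#' byte-identical for the CSV and YAML and value-identical for the TIFF.
#'
#' @param config A [simulation_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
make_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'", out_dir))
  truth <- simulate_tracks(config)
  stack <- render_video(truth, config)
  paths <- list(stack = file.path(out_dir, "stack.tif"),
                truth = file.path(out_dir, "truth.csv"),
                config = file.path(out_dir, "config.yaml"))
  write_stack(stack, paths$stack)
  write_spots_table(truth$tracks, paths$truth, layout = "diper")
  yaml::write_yaml(unclass(config), paths$config)
  invisible(paths)
}

#' Read a simulation config from YAML
#'
#' Unknown fields and invariant violations are reported by field name.
#'
#' @param path YAML file whose keys mirror [simulation_config()] arguments.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown simulation config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(simulation_config, vals)
}
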