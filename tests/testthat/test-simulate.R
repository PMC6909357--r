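test_that("fully biased zero-noise walks are perfectly straight +x", {
  # field wide enough that no cell reaches the +x boundary (no reflection)
  cfg <- simulation_config(n_cells = 5, bias_weight = 1, speed_sd = 0,
                           persistence_sd = 0, speed_mean = 5,
                           n_frames = 20, image_size = c(256, 1024), seed = 2)
  truth <- simulate_tracks(cfg)
  dirs <- directionality_ratio(truth$tracks)
  expect_equal(dirs$directionality, rep(1, 5))
  # speed 5 um/min at 2 min interval -> every step exactly 10 um
  steps <- truth$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(d = list(sqrt(diff(x)^2 + diff(y)^2))) |>
    tidyr::unnest(d)
  expect_equal(steps$d, rep(10, 5 * 19), tolerance = 1e-12)
  expect_true(all(diff(subset(truth$tracks, track_id == 1)$x) > 0))
})

test_that("unbiased populations are isotropic", {
  cfg <- simulation_config(n_cells = 200, bias_weight = 0, n_frames = 30,
                           image_size = c(512, 512), seed = 5)
  truth <- simulate_tracks(cfg)
  net <- truth$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(dx = dplyr::last(x) - dplyr::first(x),
                     dy = dplyr::last(y) - dplyr::first(y))
  sem_x <- sd(net$dx) / sqrt(nrow(net))
  sem_y <- sd(net$dy) / sqrt(nrow(net))
  expect_lt(sqrt(mean(net$dx)^2 + mean(net$dy)^2),
            3 * sqrt(sem_x^2 + sem_y^2))
  # and the mean directionality is well below 1
  expect_lt(mean(directionality_ratio(truth$tracks)$directionality), 0.8)
})

test_that("mean realized step length converges to speed_mean * interval", {
  cfg0 <- simulation_config(n_cells = 20, speed_mean = 5, speed_sd = 0,
                            n_frames = 50, image_size = c(512, 512), seed = 8)
  step_len <- function(truth) {
    truth$tracks |>
      dplyr::group_by(track_id) |>
      dplyr::summarise(d = list(sqrt(diff(x)^2 + diff(y)^2))) |>
      tidyr::unnest(d) |>
      dplyr::pull(d)
  }
  expect_equal(mean(step_len(simulate_tracks(cfg0))), 10, tolerance = 0.02)
  cfg1 <- simulation_config(n_cells = 120, speed_mean = 5, speed_sd = 1.5,
                            n_frames = 100, image_size = c(1024, 1024), seed = 9)
  expect_equal(mean(step_len(simulate_tracks(cfg1))), 10, tolerance = 0.05)
})

test_that("directionality increases strictly with chemotactic bias", {
  mean_dir <- vapply(c(0, 0.25, 0.5, 1), function(b) {
    cfg <- simulation_config(n_cells = 100, bias_weight = b, n_frames = 40,
                             image_size = c(512, 512), seed = 33)
    mean(directionality_ratio(simulate_tracks(cfg)$tracks)$directionality)
  }, numeric(1))
  expect_true(all(diff(mean_dir) > 0))
})

test_that("rendering places the intensity maximum at the true position", {
  cfg <- simulation_config(n_cells = 1, noise_sd = 0,
                           background_texture_amplitude = 0,
                           n_frames = 10, seed = 12)
  truth <- simulate_tracks(cfg)
  stack <- render_video(truth, cfg)
  for (t in 1:10) {
    fr <- unclass(stack)[, , t]
    peak <- which(fr == max(fr), arr.ind = TRUE)[1, ]
    true_pos <- truth$tracks[truth$tracks$frame == t - 1L, ]
    expect_lt(abs(peak["col"] - 1 - true_pos$x / 2), 1.0)
    expect_lt(abs(peak["row"] - 1 - true_pos$y / 2), 1.0)
  }
})

test_that("static texture without cells or noise gives identical frames", {
  cfg <- simulation_config(n_cells = 1, noise_sd = 0, vanish_probability = 0,
                           background_texture_amplitude = 20, n_frames = 4,
                           seed = 3)
  truth <- simulate_tracks(cfg)
  truth$rendered$rendered <- FALSE  # suppress all cells
  stack <- render_video(truth, cfg)
  arr <- unclass(stack)
  for (t in 2:4) expect_identical(arr[, , t], arr[, , 1])
  expect_gt(sd(arr[, , 1]), 0)
})

test_that("realized peak-to-noise ratio tracks amplitude / noise_sd", {
  cfg <- simulation_config(n_cells = 1, blob_amplitude = 150, noise_sd = 30,
                           n_frames = 10, seed = 21)
  truth <- simulate_tracks(cfg)
  stack <- render_video(truth, cfg)
  arr <- unclass(stack)
  # peak amplitude: average the pixel under the true position over frames
  # (noise at the peak is far from the zero-clip, so it averages out)
  peaks <- vapply(1:10, function(t) {
    pos <- truth$tracks[truth$tracks$frame == t - 1L, ]
    arr[round(pos$y / 2) + 1, round(pos$x / 2) + 1, t]
  }, numeric(1))
  # background noise is zero-clipped half-Gaussian far from the cell;
  # recover the underlying sigma via sd(max(N(0, s), 0)) = s * sqrt(1/2 - 1/(2*pi))
  pos <- truth$tracks[truth$tracks$frame == 0, ]
  r <- matrix(seq_len(dim(arr)[1]), dim(arr)[1], dim(arr)[2])
  cc <- matrix(seq_len(dim(arr)[2]), dim(arr)[1], dim(arr)[2], byrow = TRUE)
  far <- sqrt((r - 1 - pos$y / 2)^2 + (cc - 1 - pos$x / 2)^2) > 40
  noise <- sd(arr[, , 1][far]) / sqrt(1 / 2 - 1 / (2 * pi))
  expect_equal(mean(peaks) / noise, 150 / 30, tolerance = 0.15)
})

test_that("fixtures are deterministic and re-load cleanly", {
  cfg <- simulation_config(n_cells = 3, n_frames = 121, image_size = c(64, 64),
                           blob_diameter = 30, seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture(cfg, d1)
  p2 <- make_fixture(cfg, d2)
  expect_identical(readLines(p1$truth), readLines(p2$truth))
  s1 <- read_stack(p1$stack, cal22)
  s2 <- read_stack(p2$stack, cal22)
  expect_identical(unclass(s1), unclass(s2))
  # 121 frames at 2 min = 4 h of simulated time
  cfg_back <- read_simulation_config(p1$config)
  expect_equal((cfg_back$n_frames - 1) * cfg_back$frame_interval, 240)
  truth_back <- read_spots_table(p1$truth)
  expect_equal(n_tracks(truth_back), 3L)
})

test_that("config invariants are enforced by field name", {
  expect_error(simulation_config(bias_weight = 1.5), "bias_weight")
  expect_error(simulation_config(speed_mean = 0), "speed_mean")
  expect_error(simulation_config(n_frames = 1), "n_frames")
  expect_error(simulation_config(vanish_probability = 1), "vanish_probability")
  cfg <- simulation_config(n_cells = 1, pixel_size = 20, blob_diameter = 30)
  expect_error(render_video(simulate_tracks(cfg), cfg), "resolved")
})
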