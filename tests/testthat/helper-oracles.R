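# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code with the package internals it checks.

cal22 <- calibration(pixel_size = 2, frame_interval = 2)

# ---- assignment oracle: exhaustive enumeration over partial matchings ----
enum_assignment_cost <- function(cost, alt) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(i, used_t, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- min(best, acc + alt * (m - length(used_t)))
      return()
    }
    rec(i + 1L, used_t, acc + alt)  # source i unmatched
    for (j in seq_len(m)) {
      if (!(j %in% used_t) && is.finite(cost[i, j])) {
        rec(i + 1L, c(used_t, j), acc + cost[i, j])
      }
    }
  }
  rec(1L, integer(0), 0)
  best
}

# ---- Mann-Whitney U by O(n*m) pairwise counting ----
count_U <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

# ---- MSD by double loop ----
msd_double_loop <- function(x, y, k) {
  n <- length(x)
  acc <- 0
  for (t in seq_len(n - k)) {
    acc <- acc + (x[t + k] - x[t])^2 + (y[t + k] - y[t])^2
  }
  acc / (n - k)
}

# ---- saturation cut values by direct sort ----
quantile_cuts_oracle <- function(v, f) {
  s <- sort(v)
  n <- length(s)
  k <- floor(n * f / 2)
  c(s[k + 1], s[n - k])
}

# ---- tiny track/stack builders ----
straight_track <- function(id = 1L, n = 10L, step_x = 10, step_y = 0,
                           x0 = 0, y0 = 0) {
  tibble::tibble(track_id = id, frame = 0:(n - 1L),
                 x = x0 + step_x * (0:(n - 1L)),
                 y = y0 + step_y * (0:(n - 1L)), quality = 1)
}

random_track <- function(id, n, step_sd = 3, seed = NULL) {
  gen <- function() {
    tibble::tibble(track_id = id, frame = 0:(n - 1L),
                   x = cumsum(c(50, rnorm(n - 1L, 0, step_sd))),
                   y = cumsum(c(50, rnorm(n - 1L, 0, step_sd))),
                   quality = 1)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

constant_stack <- function(value = 7, h = 16, w = 16, t = 3, cal = cal22) {
  image_stack(array(value, dim = c(h, w, t)), cal)
}

# single Gaussian bump frame at pixel coords (row0, col0), 1-based, sub-pixel ok
bump_frame <- function(h, w, row0, col0, amplitude = 100, sd_px = 4) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  amplitude * exp(-((rr - row0)^2 + (cc - col0)^2) / (2 * sd_px^2))
}

# greedy matching of detections to ground truth within a radius (um);
# returns per-frame matched pairs for recall/precision/rmse
match_detections <- function(spots, truth_tracks, rendered, radius_um) {
  truth <- dplyr::inner_join(truth_tracks, rendered,
                             by = c("track_id", "frame")) |>
    dplyr::filter(rendered)
  frames <- sort(unique(c(spots$frame, truth$frame)))
  tp <- 0L; fp <- 0L; fn <- 0L; err2 <- numeric(0)
  for (f in frames) {
    s <- spots[spots$frame == f, ]
    g <- truth[truth$frame == f, ]
    if (nrow(s) == 0L) { fn <- fn + nrow(g); next }
    if (nrow(g) == 0L) { fp <- fp + nrow(s); next }
    d <- sqrt(outer(s$x, g$x, `-`)^2 + outer(s$y, g$y, `-`)^2)
    d[d > radius_um] <- Inf
    sol <- solve_assignment(d, alternative_cost = radius_um * 10)
    tp <- tp + nrow(sol$matches)
    fp <- fp + length(sol$unmatched_sources)
    fn <- fn + length(sol$unmatched_targets)
    if (nrow(sol$matches)) {
      err2 <- c(err2, (d[cbind(sol$matches$source, sol$matches$target)])^2)
    }
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       rmse_um = sqrt(mean(err2)))
}

# majority-vote identity check: every spot of a recovered track is assigned
# to its nearest true track; a track is "clean" if all spots agree
identity_swap_count <- function(tracks, truth_tracks) {
  truth_by_frame <- split(truth_tracks, truth_tracks$frame)
  assign_gt <- function(frame, x, y) {
    g <- truth_by_frame[[as.character(frame)]]
    g$track_id[which.min((g$x - x)^2 + (g$y - y)^2)]
  }
  gt <- mapply(assign_gt, tracks$frame, tracks$x, tracks$y)
  swaps <- tapply(gt, tracks$track_id, function(v) length(unique(v)) - 1L)
  sum(swaps)
}
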