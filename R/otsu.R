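#' Otsu's threshold for a numeric feature vector
#'
#' Classic between-class-variance maximization on a fixed-bin histogram,
#' used for the "auto" quality and duration thresholds. Deterministic:
#' ties resolve to the lowest threshold.
#'
#' @param x Numeric vector (non-finite values dropped).
#' @param n_bins Number of histogram bins.
#' @return The threshold value (a bin edge); `-Inf` if fewer than 2 distinct
#'   values, so that thresholding keeps everything.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(-Inf)
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b[-n_bins])  # first maximum = lowest threshold
  edges[k + 1L]
}
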