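# internal helpers shared across modules

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Reflect (fold) positions into [0, limit]; used for boundary handling in the
# simulator. Works for arbitrarily large excursions.
fold_reflect <- function(p, limit) {
  if (limit <= 0) stop("reflection limit must be positive", call. = FALSE)
  m <- p %% (2 * limit)
  limit - abs(limit - m)
}

# 2D convolution with symmetric (reflection) boundary padding, via FFT.
# `kernel` must have odd dimensions; its centre pixel is the origin.
conv2_reflect <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  stopifnot(nrow(kernel) == 2L * kr + 1L, ncol(kernel) == 2L * kc + 1L)
  padded <- pad_reflect(img, kr, kc)
  ph <- nrow(padded); pw <- ncol(padded)
  kpad <- matrix(0, ph, pw)
  kpad[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  # shift kernel centre to (1,1) so the output stays aligned with `padded`
  kpad <- kpad[c((kr + 1):ph, seq_len(kr)), c((kc + 1):pw, seq_len(kc)), drop = FALSE]
  out <- Re(stats::fft(stats::fft(padded) * stats::fft(kpad), inverse = TRUE)) / (ph * pw)
  out[(kr + 1):(kr + nrow(img)), (kc + 1):(kc + ncol(img)), drop = FALSE]
}

pad_reflect <- function(img, kr, kc) {
  h <- nrow(img); w <- ncol(img)
  if (kr >= h || kc >= w) {
    stop("kernel is too large for the image", call. = FALSE)
  }
  ri <- c(if (kr > 0L) kr:1L, seq_len(h), if (kr > 0L) h:(h - kr + 1L))
  ci <- c(if (kc > 0L) kc:1L, seq_len(w), if (kc > 0L) w:(w - kc + 1L))
  img[ri, ci, drop = FALSE]
}

gaussian_kernel_2d <- function(sigma, radius = ceiling(4 * sigma)) {
  ax <- (-radius):radius
  g1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid '%s': %s", field, msg))
}
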