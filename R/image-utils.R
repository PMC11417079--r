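# Small separable-filter helpers shared by the SSIM implementation and the
# procedural image corpus.  Filtering is done as banded-matrix products,
# which is plenty fast at the map sizes used here.

gauss_kernel <- function(sigma, radius) {
  w <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  w / sum(w)
}

# "valid" separable 2D filtering: output only where the window fits fully
# inside the image.
filter2_valid <- function(x, w) {
  r <- (length(w) - 1L) / 2L
  h <- nrow(x); wd <- ncol(x)
  if (h < length(w) || wd < length(w))
    stop("image smaller than the filter window")
  band <- function(n) {
    m <- matrix(0, n - 2L * r, n)
    for (i in seq_len(n - 2L * r)) m[i, i:(i + 2L * r)] <- w
    m
  }
  band(h) %*% x %*% t(band(wd))
}

# "same"-size separable smoothing with edge-truncated, renormalized
# kernels (used for corpus texture generation, where exact edge handling
# is immaterial).
gauss_smooth <- function(x, sigma) {
  r <- max(1L, as.integer(round(3 * sigma)))
  w <- gauss_kernel(sigma, r)
  band_same <- function(n) {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      wj <- w[j - i + r + 1L]
      m[i, j] <- wj / sum(wj)
    }
    m
  }
  band_same(nrow(x)) %*% x %*% t(band_same(ncol(x)))
}

# Pooled lag-1 spatial autocorrelation (rows and columns), used to
# characterize spatial structure of parameter maps.
lag1_autocorr <- function(x) {
  h <- nrow(x); w <- ncol(x)
  a <- c(x[-h, ], x[, -w])
  b <- c(x[-1, ], x[, -1])
  stats::cor(a, b)
}
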