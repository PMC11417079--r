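#' Mono-exponential forward signal model
#'
#' Evaluates `S(eta) = S0 * exp(-eta / T)` at every sampling point of the
#' schedule.  Internally the decay is computed as `exp(-eta * R)` with the
#' rate `R = 1/T`, mirroring the rate parameterization used by the fitters.
#'
#' @param s0 Scalar or matrix of signal amplitudes at `eta = 0`.
#' @param t Scalar or matrix (matching `s0`) of positive normalized time
#'   constants.
#' @param schedule An [echo_schedule()].
#' @return For scalar inputs, a vector of length `schedule$n`; for matrix
#'   inputs, an `nrow x ncol x n` array.
#' @examples
#' decay_signal(1, 0.7, echo_schedule())
#' @export
decay_signal <- function(s0, t, schedule) {
  stopifnot(inherits(schedule, "echo_schedule"))
  if (any(t <= 0)) stop("'t' must be positive everywhere")
  eta <- schedule$eta
  if (length(s0) == 1L && length(t) == 1L)
    return(as.numeric(s0) * exp(-eta / as.numeric(t)))
  s0 <- as.matrix(s0); t <- as.matrix(t)
  if (!identical(dim(s0), dim(t))) stop("'s0' and 't' must have matching dimensions")
  r <- 1 / t
  out <- array(0, c(dim(s0), schedule$n))
  for (j in seq_along(eta)) out[, , j] <- s0 * exp(-eta[j] * r)
  out
}

#' Apply Rician noise to a magnitude series
#'
#' Each pixel value `m` is replaced by `|m + g1 + i*g2|` with `g1, g2`
#' independent zero-mean Gaussians of standard deviation `sigma`: additive
#' complex Gaussian noise followed by the magnitude operation.  The result
#' is deterministic when the [noise_spec()] carries a seed.
#'
#' @param series An [image_series()].
#' @param noise A [noise_spec()].
#' @return A noisy [image_series()] on the same schedule (the `normalized`
#'   flag is cleared, as noise perturbs the maximum).
#' @export
add_rician_noise <- function(series, noise) {
  stopifnot(inherits(series, "image_series"), inherits(noise, "noise_spec"))
  dat <- rician_corrupt(series$data, noise$sigma, noise$seed)
  image_series(dat, series$schedule, normalized = FALSE)
}

# Raw array version shared with the synthetic generator and the
# noise-addition experiment.
rician_corrupt <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("'sigma' must be nonnegative")
  if (sigma == 0) return(x)
  draw <- function() {
    g1 <- rnorm(length(x), 0, sigma)
    g2 <- rnorm(length(x), 0, sigma)
    sqrt((x + g1)^2 + g2^2)
  }
  y <- if (is.null(seed)) draw() else with_seed(seed, draw())
  array(y, dim(x))
}

#' Per-pixel signal-to-noise ratio in dB
#'
#' `SNR_dB = 20 * log10( ||S(eta)||_2 / (sigma * sqrt(N)) )`, where the
#' L2 norm runs over the echo series predicted by [decay_signal()] and `N`
#' is the number of echoes.  Pixels with `s0 = 0` have no signal and map to
#' `-Inf`; the sentinel propagates through binning, where such pixels fall
#' below every finite bin edge and are excluded.
#'
#' @param s0,t Scalars or matrices of amplitudes and time constants.
#' @param sigma Positive scalar (or matrix) noise standard deviation.
#' @param schedule An [echo_schedule()].
#' @return SNR in dB, same shape as `s0`.
#' @export
snr_db <- function(s0, t, sigma, schedule) {
  stopifnot(inherits(schedule, "echo_schedule"))
  if (any(sigma <= 0)) stop("'sigma' must be strictly positive (sigma = 0 gives infinite SNR)")
  if (any(t <= 0)) stop("'t' must be positive")
  eta <- schedule$eta
  n <- schedule$n
  if (length(t) == 1L) {
    k <- sqrt(sum(exp(-2 * eta / t)))
  } else {
    t <- as.matrix(t)
    k <- 0
    for (j in seq_along(eta)) k <- k + exp(-2 * eta[j] / t)
    k <- sqrt(k)
  }
  20 * log10((s0 * k) / (sigma * sqrt(n)))
}
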