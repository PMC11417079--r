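#' Multi-echo magnitude image series
#'
#' Container for one slice's multi-echo magnitude stack: a nonnegative
#' `height x width x n` array plus the [echo_schedule()] it was sampled on,
#' and a flag recording whether the global-max normalization has been
#' applied.
#'
#' @param data Numeric 3D array, `height x width x n`, nonnegative
#'   (magnitude images).
#' @param schedule An [echo_schedule()] whose length matches `dim(data)[3]`.
#' @param normalized Logical; `TRUE` if the series has been scaled so its
#'   global maximum is 1.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, schedule, normalized = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array (height x width x n_echo)")
  if (!inherits(schedule, "echo_schedule")) stop("'schedule' must be an echo_schedule")
  if (dim(data)[3] != schedule$n)
    stop("third dimension of 'data' (", dim(data)[3],
         ") does not match schedule length (", schedule$n, ")")
  if (any(data < 0)) stop("magnitude data must be nonnegative")
  if (isTRUE(normalized) && abs(max(data) - 1) > 1e-9)
    stop("'normalized' is TRUE but the global maximum is not 1")
  structure(list(data = data, schedule = schedule, normalized = isTRUE(normalized)),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_series> ", d[1], "x", d[2], " pixels, ", d[3], " echoes",
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Per-pixel parameter maps
#'
#' Holds the pixelwise signal amplitude `s0` (signal at `eta = 0`) and
#' normalized time constant `t` (`T2 / TE_max` for T2 mapping), either as
#' ground truth or as an estimate.  The Rician fitter additionally
#' populates a per-pixel noise map `sigma_rice`.
#'
#' @param s0,t Numeric matrices of identical dimensions.
#' @param sigma_rice Optional numeric matrix of the same dimensions.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(s0, t, sigma_rice = NULL) {
  s0 <- as.matrix(s0); t <- as.matrix(t)
  if (!identical(dim(s0), dim(t)))
    stop("'s0' and 't' must have identical dimensions")
  if (!is.null(sigma_rice)) {
    sigma_rice <- as.matrix(sigma_rice)
    if (!identical(dim(sigma_rice), dim(s0)))
      stop("'sigma_rice' dimensions must match 's0'")
  }
  structure(list(s0 = s0, t = t, sigma_rice = sigma_rice), class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$s0)
  cat("<parameter_map> ", d[1], "x", d[2],
      if (!is.null(x$sigma_rice)) " (with sigma_rice)" else "", "\n", sep = "")
  cat("  s0: [", format(min(x$s0), digits = 4), ", ", format(max(x$s0), digits = 4),
      "]  t: [", format(min(x$t), digits = 4), ", ", format(max(x$t), digits = 4),
      "]\n", sep = "")
  invisible(x)
}

#' Complex-Gaussian noise specification
#'
#' The noise process applied to synthetic magnitude images: independent
#' zero-mean Gaussian noise of standard deviation `sigma` in each of the two
#' complex channels, followed by the magnitude operation (Rician noise).
#'
#' @param sigma Nonnegative scalar, noise standard deviation per channel in
#'   signal units.
#' @param seed Optional integer seed making the draw reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single nonnegative number")
  structure(list(sigma = sigma, seed = seed), class = "noise_spec")
}

#' Normalize a series to unit global maximum
#'
#' Divides the whole stack by its global maximum over all three dimensions,
#' so the largest value becomes exactly 1.  Idempotent.
#'
#' @param series An [image_series()] with at least one positive value.
#' @return The normalized [image_series()] with the `normalized` flag set.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "image_series"))
  m <- max(series$data)
  if (m <= 0) stop("cannot normalize an all-zero series")
  image_series(series$data / m, series$schedule, normalized = TRUE)
}

#' Center-crop a series and discard the first echo
#'
#' Standard preprocessing for in vivo multi-echo series: spatial center crop
#' (leading offset `floor((dim - crop)/2)` on each axis) and removal of the
#' first echo, which is the sample most contaminated by stimulated echoes.
#' The remaining schedule still ends at `eta = 1`, so it stays valid.
#'
#' @param series An [image_series()].
#' @param crop Target spatial size (pixels); cropping is the identity when
#'   the series is already `crop x crop`.
#' @param drop_first Logical; drop the first echo?  Set `FALSE` for series
#'   synthesized directly on a first-echo-free schedule.
#' @return The preprocessed [image_series()].
#' @export
preprocess_series <- function(series, crop = 128L, drop_first = TRUE) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  if (d[1] < crop || d[2] < crop)
    stop("spatial dimensions (", d[1], "x", d[2], ") smaller than crop size ", crop)
  o1 <- (d[1] - crop) %/% 2L
  o2 <- (d[2] - crop) %/% 2L
  dat <- series$data[o1 + seq_len(crop), o2 + seq_len(crop), , drop = FALSE]
  sch <- series$schedule
  if (isTRUE(drop_first)) {
    if (d[3] < 2L) stop("need at least 2 echoes to drop the first")
    dat <- dat[, , -1L, drop = FALSE]
    sch <- echo_schedule(eta = sch$eta[-1L],
                         te_ms = if (!is.null(sch$te_ms)) sch$te_ms[-1L],
                         te_max_ms = sch$te_max_ms)
  }
  # cropping can remove the global-max pixel, so the flag only survives
  # when the maximum is still exactly 1
  image_series(dat, sch,
               normalized = series$normalized && abs(max(dat) - 1) <= 1e-9)
}
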