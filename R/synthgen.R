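#' Configuration for synthetic relaxometry datasets
#'
#' Defines the study conditions under which synthetic multi-echo series are
#' generated: map size, parameter ranges, the per-series noise range, the
#' echo schedule, and the generation mode.  The defaults emulate the
#' reference conditions: 128 x 128 maps, `S0` in `[0, 1]`, `T` in
#' `[0.045, 4]`, per-series complex-Gaussian noise `sigma` drawn uniformly
#' from `[0.001, 0.1]`, and ten echoes at `eta = k/11`, `k = 2..11`.
#'
#' @param n_series Number of image series to generate.
#' @param size Spatial dimension of the square maps.
#' @param s0_range,t_range,sigma_range Length-2 ranges (lo < hi); the lower
#'   `t` bound must be positive.
#' @param schedule An [echo_schedule()].
#' @param mode `"corpus"` (ground-truth maps taken from a corpus of
#'   grayscale images, giving naturalistic spatial correlation) or
#'   `"urand"` (i.i.d. uniform pixels, no spatial correlation).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_series, size = 128L, s0_range = c(0, 1),
                         t_range = c(0.045, 4), sigma_range = c(0.001, 0.1),
                         schedule = echo_schedule(),
                         mode = c("corpus", "urand"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_series >= 1L, size >= 2L)
  chk <- function(rg, nm) {
    if (length(rg) != 2L || rg[1] >= rg[2]) stop("'", nm, "' must be an ordered range")
  }
  chk(s0_range, "s0_range"); chk(t_range, "t_range"); chk(sigma_range, "sigma_range")
  if (t_range[1] <= 0) stop("lower bound of 't_range' must be positive")
  if (sigma_range[1] < 0) stop("'sigma_range' must be nonnegative")
  stopifnot(inherits(schedule, "echo_schedule"))
  structure(list(n_series = as.integer(n_series), size = as.integer(size),
                 s0_range = s0_range, t_range = t_range,
                 sigma_range = sigma_range, schedule = schedule,
                 mode = mode, seed = as.integer(seed)),
            class = "synth_config")
}

#' Prepare a grayscale image as a parameter-map surrogate
#'
#' Converts an image to a `size x size` map spanning `[lo, hi]`: color
#' images are grayscaled by an unweighted channel mean, images smaller
#' than `size` are bilinearly upscaled (preserving aspect), the result is
#' center-cropped and min-max scaled so each prepared map covers the full
#' parameter range.  A constant image has zero dynamic range and maps to
#' the midpoint `(lo + hi)/2` with a warning.
#'
#' @param image Numeric matrix (grayscale) or `H x W x channels` array.
#' @param size Output side length (pixels).
#' @param lo,hi Output range.
#' @return A `size x size` numeric matrix with values in `[lo, hi]`.
#' @export
prepare_reference_image <- function(image, size, lo, hi) {
  stopifnot(lo < hi)
  if (is.array(image) && length(dim(image)) == 3L)
    image <- apply(image, c(1, 2), mean)
  image <- as.matrix(image)
  d <- dim(image)
  if (min(d) < size) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("image (", d[1], "x", d[2], ") smaller than ", size,
           " and EBImage is not available for upscaling")
    sc <- size / min(d)
    image <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                                w = ceiling(d[1] * sc),
                                                h = ceiling(d[2] * sc)))
    d <- dim(image)
  }
  o1 <- (d[1] - size) %/% 2L; o2 <- (d[2] - size) %/% 2L
  img <- image[o1 + seq_len(size), o2 + seq_len(size)]
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("constant-valued image: mapping to range midpoint")
    return(matrix((lo + hi) / 2, size, size))
  }
  lo + (hi - lo) * (img - rng[1]) / (rng[2] - rng[1])
}

#' Synthesize one noisy series with known ground truth
#'
#' Runs the forward model [decay_signal()] on the supplied ground-truth
#' maps and corrupts the result with Rician noise of level `sigma`.  The
#' exact input maps are stored unchanged as the record's ground truth.
#'
#' @param s0_map,t_map Ground-truth matrices of identical shape.
#' @param schedule An [echo_schedule()].
#' @param sigma Noise standard deviation (may be 0).
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `synth_record`: a list with `series`
#'   ([image_series()]), `truth` ([parameter_map()]) and `sigma`.
#' @export
synthesize_series_pair <- function(s0_map, t_map, schedule, sigma, seed = NULL) {
  s0_map <- as.matrix(s0_map); t_map <- as.matrix(t_map)
  if (!identical(dim(s0_map), dim(t_map))) stop("map shapes differ")
  clean <- decay_signal(s0_map, t_map, schedule)
  noisy <- rician_corrupt(clean, sigma, seed)
  structure(list(series = image_series(noisy, schedule),
                 truth = parameter_map(s0_map, t_map),
                 sigma = sigma),
            class = "synth_record")
}

#' Build a synthetic training/testing dataset
#'
#' Generates `n_series` independent records.  In `"corpus"` mode each
#' record uses two *distinct* corpus images (never reused within the
#' dataset) as `S0` and `T` surrogates, prepared with
#' [prepare_reference_image()]; in `"urand"` mode every pixel of both maps
#' is drawn i.i.d. uniform over the configured ranges.  Each series gets
#' its own noise level `sigma ~ Uniform(sigma_range)` and its own noise
#' stream derived from the dataset seed, so the dataset is bit-reproducible.
#'
#' @param config A [synth_config()].
#' @param corpus For `"corpus"` mode, a list of grayscale images (e.g. from
#'   [procedural_corpus()]) with at least `2 * n_series` entries.
#' @return An object of class `synth_dataset`: list with `records` (a list
#'   of `synth_record`) and `config`.
#' @export
build_synthetic_dataset <- function(config, corpus = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_series
  if (config$mode == "corpus") {
    if (is.null(corpus)) stop("'corpus' is required in corpus mode")
    if (length(corpus) < 2L * n)
      stop("corpus too small: need at least ", 2L * n, " images, got ",
           length(corpus))
  }
  draws <- with_seed(config$seed, list(
    sigma = runif(n, config$sigma_range[1], config$sigma_range[2]),
    noise_seed = sample.int(.Machine$integer.max - 1L, n),
    perm = if (config$mode == "corpus") sample.int(length(corpus)),
    urand_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    if (config$mode == "corpus") {
      s0m <- prepare_reference_image(corpus[[draws$perm[2L * i - 1L]]],
                                     config$size, config$s0_range[1],
                                     config$s0_range[2])
      tm <- prepare_reference_image(corpus[[draws$perm[2L * i]]],
                                    config$size, config$t_range[1],
                                    config$t_range[2])
    } else {
      maps <- with_seed(draws$urand_seed[i], list(
        s0 = matrix(runif(config$size^2, config$s0_range[1], config$s0_range[2]),
                    config$size, config$size),
        t = matrix(runif(config$size^2, config$t_range[1], config$t_range[2]),
                   config$size, config$size)))
      s0m <- maps$s0; tm <- maps$t
    }
    records[[i]] <- synthesize_series_pair(s0m, tm, config$schedule,
                                           draws$sigma[i], draws$noise_seed[i])
  }
  structure(list(records = records, config = config), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset>", length(x$records), "records, mode:", x$config$mode,
      " size:", x$config$size, "\n")
  invisible(x)
}

#' Procedural grayscale image corpus
#'
#' A download-free source of naturalistic-looking reference images:
#' Gaussian random fields at two length scales, overlaid with a few
#' piecewise-constant ellipses and rectangles, min-max scaled to `[0, 1]`.
#' The images have strong positive spatial autocorrelation -- the property
#' that distinguishes corpus-driven from pixelwise-random ground truth and
#' that convolutional estimators can exploit.
#'
#' @param n Number of images.
#' @param size Side length in pixels.
#' @param seed Integer seed; the corpus is reproducible from it.
#' @return A list of `n` matrices in `[0, 1]`, of class `image_corpus`.
#' @export
procedural_corpus <- function(n, size = 128L, seed = 1L) {
  stopifnot(n >= 1L, size >= 16L)
  seeds <- derive_seeds(seed, n)
  imgs <- lapply(seq_len(n), function(i) {
    with_seed(seeds[i], {
      coarse <- gauss_smooth(matrix(rnorm(size^2), size, size), size / 12)
      fine <- gauss_smooth(matrix(rnorm(size^2), size, size), size / 40)
      img <- coarse / max(1e-12, sd(coarse)) + 0.4 * fine / max(1e-12, sd(fine))
      nshape <- sample(2:5, 1)
      xg <- matrix(seq_len(size), size, size)
      yg <- t(xg)
      for (k in seq_len(nshape)) {
        val <- runif(1, -2, 2)
        cx <- runif(1, 0.15, 0.85) * size; cy <- runif(1, 0.15, 0.85) * size
        rx <- runif(1, 0.05, 0.25) * size; ry <- runif(1, 0.05, 0.25) * size
        inside <- if (runif(1) < 0.5) {
          ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1       # ellipse
        } else {
          abs(xg - cx) <= rx & abs(yg - cy) <= ry            # rectangle
        }
        img[inside] <- 0.3 * img[inside] + val
      }
      rng <- range(img)
      (img - rng[1]) / (rng[2] - rng[1])
    })
  })
  structure(imgs, class = "image_corpus")
}
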