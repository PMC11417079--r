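#' Per-slice error decomposition
#'
#' Summarizes the pixelwise signed error of a `T` map
#' (`T_pred - T_true`) into three order statistics plus a structural
#' similarity score: **bias** is the median signed error, **precision**
#' the interquartile range of the signed error (75th minus 25th
#' percentile; smaller is more precise), and **accuracy** the median
#' absolute error, which folds bias and precision together.  SSIM is
#' computed on the full `t` maps via [ssim_score()].
#'
#' @param pred,truth [parameter_map()]s (or plain `t` matrices) of
#'   matching shape.
#' @param mask Optional logical matrix selecting the pixels entering the
#'   bias/precision/accuracy statistics (SSIM always uses the full map).
#' @param data_range Dynamic range used by SSIM; defaults to the span of
#'   the `T` training range, `4 - 0.045`.
#' @return A one-row data frame with columns `bias`, `precision`,
#'   `accuracy`, `ssim`.
#' @export
summarize_errors <- function(pred, truth, mask = NULL, data_range = 3.955) {
  tp <- if (inherits(pred, "parameter_map")) pred$t else as.matrix(pred)
  tt <- if (inherits(truth, "parameter_map")) truth$t else as.matrix(truth)
  if (!identical(dim(tp), dim(tt))) stop("map shapes differ")
  err <- tp - tt
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(err))) stop("mask shape differs")
    if (!any(mask)) stop("empty mask")
    ev <- err[mask]
  } else ev <- as.vector(err)
  q <- quantile(ev, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  data.frame(bias = q[2],
             precision = q[3] - q[1],
             accuracy = median(abs(ev), na.rm = TRUE),
             ssim = ssim_score(tp, tt, data_range = data_range))
}

#' Structural similarity between two maps
#'
#' Single-scale SSIM with the standard 11-point Gaussian window
#' (`sigma = 1.5`) and stability constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`, averaged over all positions where the window fits
#' fully inside the image (Gaussian-weighted local statistics, no sample
#' covariance correction).  `L` is the `data_range`; the default is the
#' span of the `T` training range so scores are comparable across slices.
#'
#' @param pred,truth Numeric matrices of identical shape, at least
#'   11 x 11.
#' @param data_range Dynamic range `L` of the data.
#' @return A scalar in `[-1, 1]`; identical maps give exactly 1.
#' @export
ssim_score <- function(pred, truth, data_range = 3.955) {
  x <- as.matrix(pred); y <- as.matrix(truth)
  if (!identical(dim(x), dim(y))) stop("map shapes differ")
  if (identical(x, y)) return(1)
  w <- gauss_kernel(1.5, 5L)
  mx <- filter2_valid(x, w); my <- filter2_valid(y, w)
  vx <- filter2_valid(x * x, w) - mx^2
  vy <- filter2_valid(y * y, w) - my^2
  cxy <- filter2_valid(x * y, w) - mx * my
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Bin signed errors over SNR and true T
#'
#' Resolves the per-pixel signed error as a function of per-pixel SNR and
#' of the true time constant: each axis is divided into `n_bins`
#' equal-width bins spanning the observed finite range (half-open
#' `[lo, hi)` bins, final bin closed), and the median and IQR of the
#' error are computed per marginal bin and per joint 2D cell.  Pixels
#' with infinite SNR sentinels (`s0 = 0`) fall below every finite edge
#' and are excluded; empty bins carry `NA`, not zero.
#'
#' @param signed_error,snr,t_true Numeric arrays of matching length.
#' @param n_bins Number of bins per axis.
#' @return An object of class `binned_error_surface`: list with
#'   `snr_edges`, `t_edges`, marginal data frames `by_snr` and `by_t`
#'   (`median`, `iqr`, `count` per bin), joint matrices `joint_median`,
#'   `joint_iqr`, `joint_count`, and `n_used`.
#' @export
bin_errors <- function(signed_error, snr, t_true, n_bins = 100L) {
  e <- as.vector(signed_error); s <- as.vector(snr); tt <- as.vector(t_true)
  if (length(e) != length(s) || length(e) != length(tt))
    stop("input lengths differ")
  keep <- is.finite(e) & is.finite(s) & is.finite(tt)
  if (!any(keep)) stop("no pixels with finite SNR and error")
  e <- e[keep]; s <- s[keep]; tt <- tt[keep]
  edges <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1L)
  }
  se <- edges(s); te <- edges(tt)
  is_ <- findInterval(s, se, rightmost.closed = TRUE)
  it_ <- findInterval(tt, te, rightmost.closed = TRUE)
  marg <- function(idx) {
    f <- factor(idx, levels = seq_len(n_bins))
    data.frame(bin = seq_len(n_bins),
               median = as.vector(tapply(e, f, median)),
               iqr = as.vector(tapply(e, f, function(v)
                 diff(quantile(v, c(0.25, 0.75), names = FALSE)))),
               count = as.vector(table(f)))
  }
  cell <- factor(is_ + n_bins * (it_ - 1L), levels = seq_len(n_bins^2))
  jm <- matrix(as.vector(tapply(e, cell, median)), n_bins, n_bins)
  ji <- matrix(as.vector(tapply(e, cell, function(v)
    diff(quantile(v, c(0.25, 0.75), names = FALSE)))), n_bins, n_bins)
  jc <- matrix(as.vector(table(cell)), n_bins, n_bins)
  structure(list(snr_edges = se, t_edges = te,
                 by_snr = marg(is_), by_t = marg(it_),
                 joint_median = jm, joint_iqr = ji, joint_count = jc,
                 n_used = length(e)),
            class = "binned_error_surface")
}

# Coerce an estimator specification (fitting function or trained model)
# to a function series -> parameter_map.
as_estimator <- function(est) {
  if (inherits(est, "t2_nn")) {
    force(est)
    function(series) predict_map(est, series)
  } else if (is.function(est)) {
    function(series) {
      out <- est(series)
      if (inherits(out, "fit_result")) out$map else out
    }
  } else stop("estimator must be a function or a trained t2_nn model")
}

#' Noise-addition robustness experiment
#'
#' Measures how each estimation method deteriorates as Rician noise is
#' retrospectively added to normalized image series.  For every series,
#' each method's map on the original data serves as its own reference;
#' complex Gaussian noise of standard deviation `sigma_levels[j]`
#' (relative to the unit series maximum) is then added, maps are
#' re-estimated without any retraining, and the per-slice change
#' `T_added_noise - T_original` is summarized with [summarize_errors()].
#'
#' @param dataset A list of normalized [image_series()] (or a
#'   `synth_dataset`, whose series are then required to be normalized).
#' @param methods Named list of estimators: fitting functions (e.g.
#'   [fit_nlls()]) or trained `t2_nn` models.
#' @param sigma_levels Added-noise standard deviations; the printed
#'   reference range 0.02-0.08 discretized at 0.01 steps.  A level of 0
#'   reproduces the input and yields zero error by construction.
#' @param seed Integer seed for the added-noise draws.
#' @return A tidy data frame, one row per series x method x level, with
#'   the [summarize_errors()] columns.
#' @export
noise_addition_experiment <- function(dataset, methods,
                                      sigma_levels = seq(0.02, 0.08, by = 0.01),
                                      seed = 1L) {
  series_list <- if (inherits(dataset, "synth_dataset"))
    lapply(dataset$records, `[[`, "series") else dataset
  if (!length(series_list)) stop("empty dataset")
  for (s in series_list) {
    stopifnot(inherits(s, "image_series"))
    if (!s$normalized)
      stop("series must be normalized (added sigma is relative to max 1); ",
           "apply normalize_series() first")
  }
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("'methods' must be a named list")
  ests <- lapply(methods, as_estimator)
  seeds <- derive_seeds(seed, length(series_list) * length(sigma_levels))
  out <- list()
  k <- 0L
  for (i in seq_along(series_list)) {
    ser <- series_list[[i]]
    base <- lapply(ests, function(f) f(ser))
    for (j in seq_along(sigma_levels)) {
      k <- k + 1L
      sig <- sigma_levels[j]
      noisy <- if (sig == 0) ser else
        image_series(rician_corrupt(ser$data, sig, seeds[k]), ser$schedule)
      for (mn in names(ests)) {
        sm <- summarize_errors(ests[[mn]](noisy), base[[mn]])
        out[[length(out) + 1L]] <-
          cbind(data.frame(series = i, method = mn, sigma_added = sig), sm)
      }
    }
  }
  do.call(rbind, out)
}
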