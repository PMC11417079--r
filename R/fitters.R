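#' Parameter bounds for the constrained fitters
#'
#' Default bounds restrict estimates to physically reasonable values:
#' `S0` in `[0, 1000]` signal units and the rate `R = 1/T` in `[0.25, 22]`
#' inverse normalized time, equivalent to `T` in `[1/22, 4]` (about
#' `[0.045, 4]`), matching the span of the synthetic training range.
#'
#' @param s0 Length-2 numeric, lower/upper bound on `S0`.
#' @param r Length-2 numeric, lower/upper bound on `R = 1/T`.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(s0 = c(0, 1000), r = c(0.25, 22)) {
  stopifnot(length(s0) == 2L, length(r) == 2L, s0[1] < s0[2], r[1] < r[2])
  structure(list(s0 = as.numeric(s0), r = as.numeric(r)), class = "fit_bounds")
}

# ---- internal plumbing -----------------------------------------------------

# Flatten a series to a (npix x n) curve matrix, pixels in column-major
# (R-native) order.
series_to_curves <- function(series) {
  d <- dim(series$data)
  matrix(series$data, nrow = d[1] * d[2], ncol = d[3])
}

exp_model <- function(s0, r, eta) {
  E <- exp(pmin(pmax(-outer(r, eta), -700), 700))
  E * s0
}

loglin_core <- function(Y, eta) {
  Lg <- log(pmax(Y, .Machine$double.eps))
  X <- cbind(1, eta)
  B <- Lg %*% X %*% solve(crossprod(X))
  list(s0 = exp(B[, 1]), r = -B[, 2])
}

residual_rms_curves <- function(Y, s0, r, eta, dof) {
  M <- exp_model(s0, r, eta)
  sqrt(rowSums((Y - M)^2) / max(dof, 1L))
}

new_fit_result <- function(s0, r, method, rms, converged, dims,
                           sigma_rice = NULL) {
  map <- parameter_map(matrix(s0, dims[1], dims[2]),
                       matrix(1 / r, dims[1], dims[2]),
                       sigma_rice = if (!is.null(sigma_rice))
                         matrix(sigma_rice, dims[1], dims[2]))
  structure(list(map = map, method = method,
                 residual_rms = matrix(rms, dims[1], dims[2]),
                 converged = matrix(converged, dims[1], dims[2])),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> method:", x$method,
      " converged:", sum(x$converged), "/", length(x$converged), "pixels\n")
  invisible(x)
}

# Vectorized Levenberg-Marquardt for the 2-parameter exponential model,
# run simultaneously over all pixels.  Bounds (if finite) are enforced by
# projection of each candidate step.  A pixel is marked converged when its
# (projected) candidate step falls below `tol` relative size -- at an
# active bound the projected step shrinks to zero, which counts.
lm_exp2 <- function(Y, eta, s0, r, lower = c(-Inf, -Inf), upper = c(Inf, Inf),
                    max_iter = 100L, tol = 1e-8) {
  npix <- nrow(Y)
  clamp2 <- function(a, b) list(pmin(pmax(a, lower[1]), upper[1]),
                                pmin(pmax(b, lower[2]), upper[2]))
  p <- clamp2(s0, r); s0 <- p[[1]]; r <- p[[2]]
  M <- exp_model(s0, r, eta)
  cost <- rowSums((Y - M)^2)
  cost[!is.finite(cost)] <- Inf
  lam <- rep(1e-3, npix)
  conv <- logical(npix)

  for (it in seq_len(max_iter)) {
    act <- which(!conv)
    if (!length(act)) break
    Ya <- Y[act, , drop = FALSE]
    s0a <- s0[act]; ra <- r[act]; lama <- lam[act]
    E <- exp(pmin(pmax(-outer(ra, eta), -700), 700))
    Ma <- E * s0a
    Rr <- Ya - Ma
    J1 <- E
    J2 <- -sweep(Ma, 2L, eta, "*")
    A11 <- rowSums(J1 * J1); A12 <- rowSums(J1 * J2); A22 <- rowSums(J2 * J2)
    g1 <- rowSums(J1 * Rr); g2 <- rowSums(J2 * Rr)
    a <- A11 * (1 + lama); d <- A22 * (1 + lama)
    det <- a * d - A12^2
    ok <- is.finite(det) & det > 0
    d1 <- ifelse(ok, (d * g1 - A12 * g2) / det, 0)
    d2 <- ifelse(ok, (a * g2 - A12 * g1) / det, 0)
    pc <- clamp2(s0a + d1, ra + d2)
    s0c <- pc[[1]]; rc <- pc[[2]]
    stepr <- pmax(abs(s0c - s0a) / (abs(s0a) + 1e-8),
                  abs(rc - ra) / (abs(ra) + 1e-8))
    Mc <- exp_model(s0c, rc, eta)
    costc <- rowSums((Ya - Mc)^2)
    costc[!is.finite(costc)] <- Inf
    better <- costc < cost[act]
    upd <- act[better]
    s0[upd] <- s0c[better]; r[upd] <- rc[better]; cost[upd] <- costc[better]
    lam[act] <- ifelse(better, pmax(lama / 3, 1e-12), pmin(lama * 5, 1e12))
    conv[act[stepr < tol]] <- TRUE
  }
  list(s0 = s0, r = r, cost = cost, converged = conv)
}

# Vectorized damped least squares for the 3-parameter Rician-expectation
# model (S0, R, sigma_Rice); Jacobian by forward differences.
lm_rice3 <- function(Y, eta, s0, r, sg, lower, upper,
                     max_iter = 100L, tol = 1e-8) {
  npix <- nrow(Y)
  n <- length(eta)
  clamp3 <- function(p1, p2, p3) list(
    pmin(pmax(p1, lower[1]), upper[1]),
    pmin(pmax(p2, lower[2]), upper[2]),
    pmin(pmax(p3, lower[3]), upper[3]))
  model <- function(p1, p2, p3) {
    nu <- exp_model(p1, p2, eta)
    rician_mean(nu, matrix(p3, nrow = length(p3), ncol = n))
  }
  p <- clamp3(s0, r, sg); s0 <- p[[1]]; r <- p[[2]]; sg <- p[[3]]
  cost <- rowSums((Y - model(s0, r, sg))^2)
  cost[!is.finite(cost)] <- Inf
  lam <- rep(1e-3, npix)
  conv <- logical(npix)

  for (it in seq_len(max_iter)) {
    act <- which(!conv)
    if (!length(act)) break
    Ya <- Y[act, , drop = FALSE]
    p1 <- s0[act]; p2 <- r[act]; p3 <- sg[act]; lama <- lam[act]
    M <- model(p1, p2, p3)
    Rr <- Ya - M
    h1 <- 1e-6 * abs(p1) + 1e-10
    h2 <- 1e-6 * abs(p2) + 1e-10
    h3 <- 1e-6 * abs(p3) + 1e-10
    J1 <- (model(p1 + h1, p2, p3) - M) / h1
    J2 <- (model(p1, p2 + h2, p3) - M) / h2
    J3 <- (model(p1, p2, p3 + h3) - M) / h3
    a <- rowSums(J1 * J1) * (1 + lama)
    d <- rowSums(J2 * J2) * (1 + lama)
    f <- rowSums(J3 * J3) * (1 + lama) + 1e-300
    b <- rowSums(J1 * J2); cc <- rowSums(J1 * J3); e <- rowSums(J2 * J3)
    g1 <- rowSums(J1 * Rr); g2 <- rowSums(J2 * Rr); g3 <- rowSums(J3 * Rr)
    det <- a * (d * f - e^2) - b * (b * f - cc * e) + cc * (b * e - cc * d)
    ok <- is.finite(det) & abs(det) > 1e-300
    i11 <- d * f - e^2;  i12 <- cc * e - b * f; i13 <- b * e - cc * d
    i22 <- a * f - cc^2; i23 <- b * cc - a * e; i33 <- a * d - b^2
    d1 <- ifelse(ok, (i11 * g1 + i12 * g2 + i13 * g3) / det, 0)
    d2 <- ifelse(ok, (i12 * g1 + i22 * g2 + i23 * g3) / det, 0)
    d3 <- ifelse(ok, (i13 * g1 + i23 * g2 + i33 * g3) / det, 0)
    pc <- clamp3(p1 + d1, p2 + d2, p3 + d3)
    stepr <- pmax(abs(pc[[1]] - p1) / (abs(p1) + 1e-8),
                  abs(pc[[2]] - p2) / (abs(p2) + 1e-8),
                  abs(pc[[3]] - p3) / (abs(p3) + 1e-8))
    Mc <- model(pc[[1]], pc[[2]], pc[[3]])
    costc <- rowSums((Ya - Mc)^2)
    costc[!is.finite(costc)] <- Inf
    better <- costc < cost[act]
    upd <- act[better]
    s0[upd] <- pc[[1]][better]; r[upd] <- pc[[2]][better]; sg[upd] <- pc[[3]][better]
    cost[upd] <- costc[better]
    lam[act] <- ifelse(better, pmax(lama / 3, 1e-12), pmin(lama * 5, 1e12))
    conv[act[stepr < tol]] <- TRUE
  }
  list(s0 = s0, r = r, sg = sg, cost = cost, converged = conv)
}

# ---- the four fitters ------------------------------------------------------

#' Log-linear fit of the decay curve
#'
#' Fits a straight line to `log S(eta)` by ordinary least squares, per
#' pixel: the slope is `-R` and the intercept `log S0`.  Nonpositive
#' samples are clamped to a machine-epsilon floor before taking the log,
#' so the fit is total; no bounds are applied and no weighting is used
#' (the log transform implicitly up-weights high-signal points).
#' This fast linearized fit also provides the initial guesses for all
#' iterative fitters.
#'
#' @param series An [image_series()] with at least 2 echoes.
#' @return A `fit_result` with fields `map` ([parameter_map()]), `method`,
#'   `residual_rms` (RMS of the residual on the original signal scale,
#'   degrees-of-freedom corrected) and `converged`.
#' @export
fit_loglin <- function(series) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  if (d[3] < 2L) stop("need at least 2 echoes")
  eta <- series$schedule$eta
  Y <- series_to_curves(series)
  ll <- loglin_core(Y, eta)
  rms <- residual_rms_curves(Y, ll$s0, ll$r, eta, d[3] - 2L)
  new_fit_result(ll$s0, ll$r, "FIT_LOGLIN", rms,
                 is.finite(ll$s0) & is.finite(ll$r), d)
}

#' Unbounded nonlinear least-squares fit
#'
#' Per-pixel Levenberg-Marquardt estimation of `(S0, R)` (with `R = 1/T`
#' fit rather than `T` to avoid division-by-zero) minimizing the
#' least-squares residual of the mono-exponential model, initialized from
#' [fit_loglin()].  Pixels that fail to converge within `max_iter`
#' iterations are flagged and retain their log-linear estimate.
#'
#' @param series An [image_series()] with at least 2 echoes.
#' @param max_iter Maximum iterations per pixel.
#' @param tol Relative step-size convergence tolerance.
#' @return A `fit_result`; see [fit_loglin()].
#' @export
fit_nlls <- function(series, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  if (d[3] < 2L) stop("need at least 2 echoes")
  eta <- series$schedule$eta
  Y <- series_to_curves(series)
  ll <- loglin_core(Y, eta)
  s0i <- pmin(pmax(ll$s0, 1e-8), 1e8)
  ri <- pmin(pmax(ll$r, -100), 1e4)
  fit <- lm_exp2(Y, eta, s0i, ri, max_iter = max_iter, tol = tol)
  bad <- !fit$converged
  fit$s0[bad] <- ll$s0[bad]
  fit$r[bad] <- ll$r[bad]
  rms <- residual_rms_curves(Y, fit$s0, fit$r, eta, d[3] - 2L)
  new_fit_result(fit$s0, fit$r, "FIT_NLLS", rms, fit$converged, d)
}

#' Bounded nonlinear least-squares fit
#'
#' As [fit_nlls()], but every Levenberg-Marquardt step is projected onto
#' the box constraints of [fit_bounds()], restricting the estimates to
#' physically reasonable values (`T` within the synthesis range).
#' Out-of-bounds initial guesses are projected into the box.
#'
#' @inheritParams fit_nlls
#' @param bounds A [fit_bounds()].
#' @return A `fit_result` whose map satisfies the bounds everywhere.
#' @export
fit_nlls_bound <- function(series, bounds = fit_bounds(),
                           max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(series, "image_series"), inherits(bounds, "fit_bounds"))
  d <- dim(series$data)
  if (d[3] < 2L) stop("need at least 2 echoes")
  eta <- series$schedule$eta
  Y <- series_to_curves(series)
  ll <- loglin_core(Y, eta)
  lo <- c(bounds$s0[1], bounds$r[1]); hi <- c(bounds$s0[2], bounds$r[2])
  fit <- lm_exp2(Y, eta, ll$s0, ll$r, lower = lo, upper = hi,
                 max_iter = max_iter, tol = tol)
  bad <- !fit$converged
  fit$s0[bad] <- pmin(pmax(ll$s0[bad], lo[1]), hi[1])
  fit$r[bad] <- pmin(pmax(ll$r[bad], lo[2]), hi[2])
  rms <- residual_rms_curves(Y, fit$s0, fit$r, eta, d[3] - 2L)
  new_fit_result(fit$s0, fit$r, "FIT_NLLS_BOUND", rms, fit$converged, d)
}

#' Rician-expectation nonlinear fit
#'
#' Fits three parameters per pixel -- `S0`, `R` and the noise level
#' `sigma_Rice` -- by minimizing the residual between the measured
#' magnitudes and the *expectation value* of the Rice distribution,
#' [rician_mean()].  This approximate correction accounts for the noise
#' floor of magnitude data without a full maximum-likelihood fit.  `S0`
#' and `R` use the same bounds as [fit_nlls_bound()]; `sigma_Rice` is
#' bounded to `[0, sigma_upper]` and initialized from the log-linear
#' residual RMS.
#'
#' @inheritParams fit_nlls_bound
#' @param sigma_upper Upper bound for `sigma_Rice` (signal units).
#' @return A `fit_result` whose map carries a populated `sigma_rice`.
#' @export
fit_nlls_rice <- function(series, bounds = fit_bounds(), sigma_upper = 10,
                          max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(series, "image_series"), inherits(bounds, "fit_bounds"))
  d <- dim(series$data)
  if (d[3] < 3L) stop("need at least 3 echoes to fit three parameters")
  eta <- series$schedule$eta
  Y <- series_to_curves(series)
  ll <- loglin_core(Y, eta)
  sgi <- pmin(pmax(residual_rms_curves(Y, ll$s0, ll$r, eta, d[3] - 2L), 1e-6),
              sigma_upper)
  lo <- c(bounds$s0[1], bounds$r[1], 0)
  hi <- c(bounds$s0[2], bounds$r[2], sigma_upper)
  fit <- lm_rice3(Y, eta, ll$s0, ll$r, sgi, lower = lo, upper = hi,
                  max_iter = max_iter, tol = tol)
  bad <- !fit$converged
  fit$s0[bad] <- pmin(pmax(ll$s0[bad], lo[1]), hi[1])
  fit$r[bad] <- pmin(pmax(ll$r[bad], lo[2]), hi[2])
  nu <- exp_model(fit$s0, fit$r, eta)
  Mfit <- rician_mean(nu, matrix(fit$sg, nrow = length(fit$sg), ncol = d[3]))
  rms <- sqrt(rowSums((Y - Mfit)^2) / max(d[3] - 3L, 1L))
  new_fit_result(fit$s0, fit$r, "FIT_NLLS_RICE", rms, fit$converged, d,
                 sigma_rice = fit$sg)
}

#' Estimate the per-pixel noise level from fit residuals
#'
#' The per-pixel noise standard deviation is estimated as the
#' degrees-of-freedom-corrected root-mean-square residual between the
#' measured curve and the fitted mono-exponential, `sqrt(SS / (n - 2))`.
#' Combined with [snr_db()], this reproduces the residual-based SNR
#' protocol used for measured data where the true noise is unknown.
#'
#' @param series The [image_series()] the fit was produced on.
#' @param fit A `fit_result` for that series.
#' @return A matrix of estimated `sigma`, same spatial shape as the series.
#' @export
estimate_sigma_map <- function(series, fit) {
  stopifnot(inherits(series, "image_series"), inherits(fit, "fit_result"))
  d <- dim(series$data)
  if (!identical(dim(fit$map$s0), d[1:2]))
    stop("fit dimensions do not match the series")
  eta <- series$schedule$eta
  Y <- series_to_curves(series)
  s0 <- as.vector(fit$map$s0)
  r <- 1 / as.vector(fit$map$t)
  sig <- residual_rms_curves(Y, s0, r, eta, d[3] - 2L)
  matrix(sig, d[1], d[2])
}
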