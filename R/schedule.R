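#' Echo schedule: the normalized sampling dimension
#'
#' An echo schedule records the dimensionless sampling points `eta` at which a
#' mono-exponential decay is observed.  For T2 mapping, `eta = TE / TE_max`,
#' so the last sample is always at `eta = 1` and the decay constant is
#' expressed in units of the maximum echo time.  The default schedule is the
#' ten-echo grid `eta = k/11` for `k = 2..11`, i.e. an eleven-echo
#' equally-spaced acquisition with the first echo discarded.
#'
#' @param eta Strictly ascending vector of positive sampling points with
#'   `max(eta) == 1`.  Ignored when `te_ms` is given.
#' @param te_ms Optional vector of physical echo times in milliseconds;
#'   `eta` is derived as `te_ms / te_max_ms`.
#' @param te_max_ms Optional scalar, the maximum echo time in milliseconds.
#'   Defaults to `max(te_ms)` when echo times are supplied.
#' @return An object of class `echo_schedule` with fields `eta`, `te_ms`,
#'   `te_max_ms` and `n`.
#' @examples
#' echo_schedule()                      # the 10-echo synthesis default
#' echo_schedule(te_ms = seq(13.2, 145.2, by = 13.2))
#' @export
echo_schedule <- function(eta = (2:11) / 11, te_ms = NULL, te_max_ms = NULL) {
  if (!is.null(te_ms)) {
    if (is.null(te_max_ms)) te_max_ms <- max(te_ms)
    eta <- te_ms / te_max_ms
  }
  eta <- as.numeric(eta)
  if (length(eta) < 1L || anyNA(eta)) stop("'eta' must be a non-empty numeric vector")
  if (any(eta <= 0)) stop("all 'eta' must be positive")
  if (is.unsorted(eta, strictly = TRUE)) stop("'eta' must be strictly ascending")
  if (abs(max(eta) - 1) > 1e-12) stop("max(eta) must equal 1 (normalized sampling)")
  if (!is.null(te_ms) && !is.null(te_max_ms)) {
    if (max(abs(eta - te_ms / te_max_ms)) > 1e-12)
      stop("'eta' inconsistent with te_ms / te_max_ms")
  }
  structure(
    list(eta = eta, te_ms = te_ms, te_max_ms = te_max_ms, n = length(eta)),
    class = "echo_schedule"
  )
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat("<echo_schedule> n =", x$n, "\n  eta:", format(x$eta, digits = 4), "\n")
  if (!is.null(x$te_max_ms))
    cat("  TE_max:", x$te_max_ms, "ms\n")
  invisible(x)
}

#' @export
format.echo_schedule <- function(x, ...) {
  paste0("echo_schedule(n=", x$n, ")")
}

schedules_equal <- function(a, b, tol = 1e-9) {
  a$n == b$n && max(abs(a$eta - b$eta)) <= tol
}
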