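sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a multi-echo series from disk
#'
#' Reads a 4D NIfTI volume (height x width x 1 x echoes, or
#' height x width x echoes) together with its JSON sidecar, which must
#' carry the echo times in milliseconds (field `te_ms`).  The schedule is
#' normalized so `max(eta) = 1`.  Echo metadata is required: a missing
#' sidecar is an error, never a silent default.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return An [image_series()].
#' @export
load_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing echo-time sidecar: expected ", sc,
         " with field 'te_ms' (echo times in milliseconds)")
  meta <- jsonlite::fromJSON(sc)
  if (is.null(meta$te_ms)) stop("sidecar ", sc, " lacks the 'te_ms' field")
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  d <- dim(arr)
  # strip NIfTI metadata attributes; the series carries plain numeric data
  if (length(d) == 4L) d <- c(d[1], d[2], d[4])
  if (length(d) != 3L) stop("expected a 3D or 4D volume")
  arr <- array(as.vector(arr), d)
  sched <- echo_schedule(te_ms = as.numeric(meta$te_ms))
  image_series(arr, sched, normalized = isTRUE(meta$normalized))
}

#' Write a multi-echo series to disk
#'
#' Writes the stack as NIfTI plus a JSON sidecar with the echo metadata
#' (physical `te_ms` when known, otherwise the normalized `eta` scaled to
#' a unit `te_max`), so a round trip through [load_series()] restores the
#' series bit-identically.
#'
#' @param series An [image_series()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  sch <- series$schedule
  te <- if (!is.null(sch$te_ms)) sch$te_ms else sch$eta
  RNifti::writeNifti(RNifti::asNifti(series$data), path)
  jsonlite::write_json(list(te_ms = te, te_max_ms = sch$te_max_ms,
                            normalized = series$normalized),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save fitted or predicted parameter maps
#'
#' Writes the `s0` and `t` maps (and `sigma_rice` when present) as NIfTI
#' files sharing a prefix, plus a JSON metadata file recording the method
#' and the echo schedule.  When the schedule carries a physical
#' `te_max_ms`, the physical relaxation-time map `t2_ms = t * te_max_ms`
#' is written alongside the normalized map.
#'
#' @param result A `fit_result` or [parameter_map()].
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_s0.nii.gz`, `<prefix>_t.nii.gz`, etc.
#' @param schedule Optional [echo_schedule()] providing `te_max_ms`
#'   (taken from the fit metadata when omitted).
#' @return The metadata path, invisibly.
#' @export
save_fit <- function(result, prefix, schedule = NULL) {
  map <- if (inherits(result, "fit_result")) result$map else result
  stopifnot(inherits(map, "parameter_map"))
  wr <- function(m, tag)
    RNifti::writeNifti(RNifti::asNifti(m), paste0(prefix, "_", tag, ".nii.gz"))
  wr(map$s0, "s0")
  wr(map$t, "t")
  te_max <- if (!is.null(schedule)) schedule$te_max_ms
  if (!is.null(te_max)) wr(map$t * te_max, "t2ms")
  if (!is.null(map$sigma_rice)) wr(map$sigma_rice, "sigma")
  meta <- list(method = if (inherits(result, "fit_result")) result$method,
               te_max_ms = te_max,
               has_sigma_rice = !is.null(map$sigma_rice),
               dims = dim(map$s0))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Load parameter maps written by [save_fit()]
#'
#' @param prefix The path prefix used when saving.
#' @return A [parameter_map()].
#' @export
load_fit <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  rd <- function(tag)
    matrix(as.array(RNifti::readNifti(paste0(prefix, "_", tag, ".nii.gz"))),
           meta$dims[1], meta$dims[2])
  parameter_map(rd("s0"), rd("t"),
                sigma_rice = if (isTRUE(meta$has_sigma_rice)) rd("sigma"))
}

#' Convert normalized time-constant bounds to physical units
#'
#' Maps the rate bounds of [fit_bounds()] through a physical echo
#' schedule: `T = 1/R` in units of `TE_max`, so the physical range is
#' `[TE_max / r_hi, TE_max / r_lo]` milliseconds.  With the default
#' bounds (`R` in `[0.25, 22]`) and an eleven-echo 13.2-145.2 ms
#' acquisition this gives 6.6-580.8 ms -- equivalently 0.25 times the
#' shortest retained echo time up to 4 times the longest.
#'
#' @param bounds A [fit_bounds()].
#' @param schedule An [echo_schedule()] with `te_max_ms` set.
#' @return Length-2 numeric, the physical `T2` range in milliseconds.
#' @export
physical_t_bounds <- function(bounds = fit_bounds(), schedule) {
  stopifnot(inherits(bounds, "fit_bounds"), inherits(schedule, "echo_schedule"))
  if (is.null(schedule$te_max_ms))
    stop("schedule has no physical te_max_ms")
  c(schedule$te_max_ms / bounds$r[2], schedule$te_max_ms / bounds$r[1])
}

#' Persist a synthetic dataset
#'
#' Stores the records in an R-native container next to a human-readable
#' JSON manifest echoing the full generation config and seed, so a
#' dataset can be regenerated or audited.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset, file.path(dir, "records.rds"))
  cfg <- dataset$config
  manifest <- list(n_series = cfg$n_series, size = cfg$size,
                   s0_range = cfg$s0_range, t_range = cfg$t_range,
                   sigma_range = cfg$sigma_range, mode = cfg$mode,
                   seed = cfg$seed, eta = cfg$schedule$eta,
                   created = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(utils::packageVersion("t2relax")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset written by [save_dataset()]
#' @param dir The dataset directory.
#' @return A `synth_dataset`.
#' @export
load_dataset <- function(dir) {
  ds <- readRDS(file.path(dir, "records.rds"))
  stopifnot(inherits(ds, "synth_dataset"))
  ds
}
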