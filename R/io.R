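#' Acquisition metadata for a cine phase-contrast series
#'
#' Describes how stored phase values map to velocities. The convention is
#' linear and symmetric: the declared integer `phase_range`
#' `(stored_min, stored_max)` maps onto `(-venc, +venc)`, so
#' `v = venc * (2 * (p - stored_min) / (stored_max - stored_min) - 1)`.
#' Positive velocity is craniocaudal. Vendor DICOM phase conventions are
#' deliberately out of scope; the sidecar is the single source of truth.
#'
#' @param venc Velocity-encoding limit, cm/s (> 0).
#' @param pixel_spacing Pixel edge length, mm.
#' @param n_frames Number of cardiac frames (>= 4).
#' @param cycle_duration Cardiac cycle duration, seconds.
#' @param slice_thickness Slice thickness, mm (informational only).
#' @param phase_range Integer length-2 `(stored_min, stored_max)`.
#' @param site_label `"aqueduct"`, `"cervical"` or any other label.
#' @param seed Optional integer provenance seed (phantom-generated data).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(venc, pixel_spacing, n_frames, cycle_duration,
                             slice_thickness = 5,
                             phase_range = c(-4096L, 4096L),
                             site_label = "aqueduct", seed = NULL) {
  if (venc <= 0) stop("venc must be positive")
  if (n_frames < 4L) stop("n_frames must be at least 4")
  if (cycle_duration <= 0) stop("cycle_duration must be positive")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  stopifnot(length(phase_range) == 2L)
  if (phase_range[1] >= phase_range[2])
    stop("phase_range stored_min must be below stored_max")
  structure(list(venc = venc, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 n_frames = as.integer(n_frames),
                 cycle_duration = cycle_duration,
                 phase_range = as.numeric(phase_range),
                 phase_convention = "linear_symmetric_v1",
                 site_label = site_label, seed = seed),
            class = "acquisition_meta")
}

#' Construct a cine phase-contrast series
#'
#' @param phase Numeric array `(row, col, frame)` of stored phase values,
#'   all within the metadata's declared `phase_range`.
#' @param meta An [acquisition_meta()].
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(phase, meta) {
  stopifnot(inherits(meta, "acquisition_meta"), is.array(phase),
            length(dim(phase)) == 3L)
  if (dim(phase)[3] != meta$n_frames)
    stop("frame-count mismatch: stack has ", dim(phase)[3],
         " frames but metadata declares ", meta$n_frames)
  pr <- meta$phase_range
  if (any(phase < pr[1] - 1e-9) || any(phase > pr[2] + 1e-9))
    stop("stored phase values fall outside the declared phase_range [",
         pr[1], ", ", pr[2], "]")
  structure(list(phase = phase, meta = meta), class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$phase)
  cat("cine phase-contrast series: ", d[1], "x", d[2], " pixels, ",
      d[3], " frames\n", sep = "")
  cat("  site: ", x$meta$site_label, ", VENC ", x$meta$venc,
      " cm/s, pixel ", x$meta$pixel_spacing, " mm, cycle ",
      x$meta$cycle_duration, " s\n", sep = "")
  invisible(x)
}

#' Convert between stored phase and velocity
#'
#' `phase_to_velocity()` decodes a [cine_series()] into a `velocity_field`
#' under the linear VENC convention; `velocity_to_phase()` is its inverse
#' on raw values (used when writing). With `quantize = TRUE` the emitted
#' phase is rounded to the integer grid, which is lossless to reconvert
#' for values originating on that grid.
#'
#' @param series A `cine_series`.
#' @return `phase_to_velocity()`: an object of class `velocity_field` with
#'   elements `v` (cm/s array), `meta`, and provenance flags
#'   `aliasing_corrected`, `background_corrected`.
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "cine_series"))
  pr <- series$meta$phase_range
  v <- series$meta$venc *
    (2 * (series$phase - pr[1]) / (pr[2] - pr[1]) - 1)
  velocity_field(v, series$meta)
}

#' @rdname phase_to_velocity
#' @param v Numeric array or vector of velocities, cm/s.
#' @param meta An [acquisition_meta()].
#' @param quantize Round stored phase to integers.
#' @export
velocity_to_phase <- function(v, meta, quantize = FALSE) {
  pr <- meta$phase_range
  p <- pr[1] + (v / meta$venc + 1) / 2 * (pr[2] - pr[1])
  if (quantize) p <- round(p)
  p
}

#' Construct a velocity field
#'
#' @param v Numeric array `(row, col, frame)`, cm/s.
#' @param meta An [acquisition_meta()].
#' @param aliasing_corrected,background_corrected Provenance flags.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(v, meta, aliasing_corrected = FALSE,
                           background_corrected = FALSE) {
  stopifnot(is.array(v), length(dim(v)) == 3L, inherits(meta, "acquisition_meta"))
  structure(list(v = v, meta = meta,
                 aliasing_corrected = aliasing_corrected,
                 background_corrected = background_corrected),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat("velocity field: ", d[1], "x", d[2], " pixels, ", d[3], " frames",
      " (aliasing_corrected=", x$aliasing_corrected,
      ", background_corrected=", x$background_corrected, ")\n", sep = "")
  invisible(x)
}

#' Write a cine series to NIfTI plus a JSON sidecar
#'
#' The stack is written as a 3-D `(x, y, t)` NIfTI volume; acquisition
#' metadata (VENC, pixel spacing, timing, phase convention) go to a JSON
#' sidecar, which is the authoritative source on reading.
#'
#' @param series A [cine_series()].
#' @param path Output NIfTI path (`.nii`).
#' @param sidecar_path Output JSON path; defaults to `path` with a
#'   `.json` extension appended.
#' @return Invisibly, `c(path, sidecar_path)`.
#' @export
write_cine <- function(series, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(series, "cine_series"))
  m <- series$meta
  img <- RNifti::asNifti(series$phase)
  RNifti::pixdim(img) <- c(m$pixel_spacing, m$pixel_spacing,
                           m$cycle_duration / m$n_frames)
  RNifti::writeNifti(img, path)
  sidecar <- list(schema = "csfflow-cine-sidecar-1",
                  venc = m$venc, pixel_spacing = m$pixel_spacing,
                  slice_thickness = m$slice_thickness, n_frames = m$n_frames,
                  cycle_duration = m$cycle_duration,
                  phase_range = m$phase_range,
                  phase_convention = m$phase_convention,
                  site_label = m$site_label, seed = m$seed)
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(path, sidecar_path))
}

#' Read a cine series from NIfTI plus its JSON sidecar
#'
#' @param path NIfTI path.
#' @param sidecar_path JSON sidecar path.
#' @return A validated [cine_series()].
#' @export
read_cine <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  if (!file.exists(sidecar_path)) stop("sidecar file not found: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("venc", "pixel_spacing", "n_frames", "cycle_duration",
                "phase_range")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop("sidecar is missing required field(s): ",
         paste(sQuote(missing), collapse = ", "))
  img <- RNifti::readNifti(path)
  stack <- array(as.numeric(img), dim = dim(img))
  if (length(dim(stack)) != 3L)
    stop("expected a 3-D (x, y, t) stack; got ", length(dim(stack)), " dims")
  if (dim(stack)[3] != sc$n_frames)
    stop("frame-count mismatch: stack has ", dim(stack)[3],
         " frames but sidecar declares ", sc$n_frames)
  meta <- acquisition_meta(venc = sc$venc, pixel_spacing = sc$pixel_spacing,
                           n_frames = sc$n_frames,
                           cycle_duration = sc$cycle_duration,
                           slice_thickness = sc$slice_thickness %||% 5,
                           phase_range = sc$phase_range,
                           site_label = sc$site_label %||% "unknown",
                           seed = sc$seed)
  cine_series(stack, meta)
}

#' Write a flow curve to CSV
#'
#' @param curve A [flow_curve][compute_flow_curve] object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_flow_curve <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  utils::write.csv(data.frame(frame_index = seq_along(curve$flow_ml_s) - 1L,
                              time_s = curve$time_s,
                              flow_ml_s = curve$flow_ml_s),
                   path, row.names = FALSE)
  invisible(path)
}
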