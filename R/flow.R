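#' Define a static background region
#'
#' A set of presumed-static pixels near the ROI used to estimate and
#' remove the eddy-current velocity baseline. Give either a rectangle
#' (`rows`/`cols`) or an explicit logical matrix (`pixels`).
#'
#' @param rows,cols Integer length-2 inclusive ranges (rectangle form).
#' @param pixels Logical matrix over the image grid (explicit form).
#' @param dim Image dimensions `(rows, cols)`; required for the
#'   rectangle form.
#' @return An object of class `background_region` holding a logical
#'   pixel matrix.
#' @export
background_region <- function(rows = NULL, cols = NULL, pixels = NULL,
                              dim = NULL) {
  if (is.null(pixels)) {
    if (is.null(rows) || is.null(cols) || is.null(dim))
      stop("give either 'pixels' or 'rows'+'cols'+'dim'")
    pixels <- matrix(FALSE, dim[1], dim[2])
    pixels[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  }
  stopifnot(is.logical(pixels), is.matrix(pixels))
  if (!any(pixels)) stop("background region is empty")
  structure(list(pixels = pixels), class = "background_region")
}

#' Square-ring background around a point
#'
#' Convenience constructor: all pixels whose Chebyshev distance from
#' `center` lies in `[inner, outer]`. A ring that is symmetric about the
#' region of interest averages a planar eddy field to its value at the
#' center, which is what makes the per-frame mean subtraction cancel the
#' offset seen by the CSF mask.
#'
#' @param center Numeric length-2 `(row, col)`.
#' @param inner,outer Chebyshev radii in pixels, `inner <= outer`.
#' @param dim Image dimensions.
#' @return A [background_region()].
#' @export
background_ring <- function(center, inner, outer, dim) {
  stopifnot(inner <= outer)
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  d <- pmax(abs(r - center[1]), abs(c - center[2]))
  background_region(pixels = d >= inner & d <= outer)
}

#' Remove the eddy-current baseline using a background region
#'
#' Eddy currents add a spatially smooth, temporally constant spurious
#' velocity offset. For each frame, the mean velocity over the background
#' pixels is subtracted from every pixel, calibrating static tissue to
#' zero velocity.
#'
#' @param field A [velocity_field()].
#' @param bg A [background_region()].
#' @param mask Optional [segmentation_mask][segment_by_threshold]; if
#'   given, an overlap between background and mask is an error.
#' @return The corrected `velocity_field` with
#'   `background_corrected = TRUE`.
#' @export
background_correct <- function(field, bg, mask = NULL) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(bg, "background_region"))
  d <- dim(field$v)
  if (!identical(dim(bg$pixels), d[1:2]))
    stop("background region dimensions do not match the field")
  if (!is.null(mask) && any(bg$pixels & mask$mask))
    stop("background region overlaps the CSF mask")
  idx <- which(bg$pixels)
  v <- field$v
  for (k in seq_len(d[3])) {
    vk <- v[, , k]
    v[, , k] <- vk - mean(vk[idx])
  }
  velocity_field(v, field$meta, aliasing_corrected = field$aliasing_corrected,
                 background_corrected = TRUE)
}

#' Reconstruct the volumetric flow curve over the CSF mask
#'
#' For each of the `N` frames, sums velocity times pixel area over the
#' mask: `Q(k) = sum_mask v * a`, with 1 cm/s over 1 mm2 equal to
#' 0.01 mL/s. The curve has one sample per reconstructed frame across
#' the averaged cardiac cycle.
#'
#' @param field A [velocity_field()]; a warning is issued if it has not
#'   been background-corrected.
#' @param mask A non-empty [segmentation_mask][segment_by_threshold].
#' @return An object of class `flow_curve`: `flow_ml_s`, `time_s`,
#'   `cycle_duration`, `site_label`.
#' @export
compute_flow_curve <- function(field, mask) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!any(mask$mask)) stop("cannot compute a flow curve over an empty mask")
  if (!field$background_corrected)
    warning("velocity field has not been background-corrected; ",
            "eddy-current offsets will bias the flow curve")
  d <- dim(field$v)
  idx <- which(mask$mask)
  area_ml <- field$meta$pixel_spacing^2 * 0.01  # mm2 * (0.01 mL/s per cm/s mm2)
  q <- vapply(seq_len(d[3]), function(k) sum(field$v[, , k][idx]) * area_ml,
              numeric(1))
  n <- d[3]
  structure(list(flow_ml_s = q,
                 time_s = (seq_len(n) - 1) * field$meta$cycle_duration / n,
                 cycle_duration = field$meta$cycle_duration,
                 site_label = field$meta$site_label),
            class = "flow_curve")
}

#' Flow curve from raw samples
#'
#' Wraps an already-computed 32-point (or N-point) flow waveform as a
#' `flow_curve`, e.g. for closed-form test signals.
#'
#' @param flow_ml_s Numeric vector of flow samples, mL/s.
#' @param cycle_duration Cycle duration, seconds.
#' @param site_label Site annotation.
#' @return A `flow_curve`.
#' @export
flow_curve <- function(flow_ml_s, cycle_duration, site_label = "unknown") {
  n <- length(flow_ml_s)
  if (n < 4L) stop("flow curve needs at least 4 samples")
  if (cycle_duration <= 0) stop("cycle_duration must be positive")
  structure(list(flow_ml_s = flow_ml_s,
                 time_s = (seq_len(n) - 1) * cycle_duration / n,
                 cycle_duration = cycle_duration, site_label = site_label),
            class = "flow_curve")
}

#' Stroke volume from a flow curve
#'
#' Integrates the positive and negative lobes of the flow waveform by
#' trapezoidal quadrature on the periodic grid (the cycle is closed from
#' the last frame back to the first, which on a uniform periodic grid
#' reduces to the mean times the period): `V+ = int max(Q, 0) dt`,
#' `V- = int max(-Q, 0) dt`. The stroke volume is the mean displaced
#' volume of the two directions, `sv = (V+ + V-) / 2`, the standard
#' back-and-forth reading of pulsatile CSF displacement; the net volume
#' `V+ - V-` (physiologic net flow, e.g. CSF production at the aqueduct)
#' is reported, not suppressed.
#'
#' @param curve A [flow_curve()].
#' @return An object of class `stroke_volume`: `sv_ul`, `v_plus_ul`,
#'   `v_minus_ul`, `net_ul` (all uL per cardiac cycle), `site_label`.
#' @export
compute_stroke_volume <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  q <- curve$flow_ml_s
  if (any(!is.finite(q))) stop("flow curve contains non-finite samples")
  h <- curve$cycle_duration / length(q)
  v_plus <- 1000 * h * sum(pmax(q, 0))   # mL -> uL
  v_minus <- 1000 * h * sum(pmax(-q, 0))
  structure(list(sv_ul = (v_plus + v_minus) / 2,
                 v_plus_ul = v_plus, v_minus_ul = v_minus,
                 net_ul = v_plus - v_minus,
                 site_label = curve$site_label),
            class = "stroke_volume")
}

#' @export
print.stroke_volume <- function(x, ...) {
  cat(sprintf("stroke volume (%s): %.1f uL/cc (V+ %.1f, V- %.1f, net %+.1f uL)\n",
              x$site_label, x$sv_ul, x$v_plus_ul, x$v_minus_ul, x$net_ul))
  invisible(x)
}
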