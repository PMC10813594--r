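#' Quantify CSF flow from a cine phase-contrast series
#'
#' Runs the full single-site pipeline: decode phase to velocity, build
#' the cardiac-fundamental parametric image over the ROI, threshold it to
#' the CSF mask, detect and (optionally) correct velocity aliasing,
#' remove the eddy-current baseline with a background region, reconstruct
#' the flow curve over the mask and integrate it to the stroke volume.
#'
#' @param series A [cine_series()] (e.g. from [generate_cine_series()] or
#'   [read_cine()]).
#' @param roi A [rect_roi()], or `NULL` for the whole image.
#' @param threshold Amplitude threshold in cm/s, or `"otsu"` to take
#'   [suggest_threshold()].
#' @param background A [background_region()], or `NULL` to skip
#'   eddy-current correction (a warning will note the uncorrected curve).
#' @param alpha Aliasing-detection magnitude fraction, see
#'   [detect_aliasing()].
#' @param max_aliased_fraction,min_aliased_pixels Aliasing-correction
#'   policy limits, see [correct_aliasing()].
#' @param correct_alias Apply aliasing correction when any samples are
#'   flagged.
#' @return A list: `velocity` (final corrected field), `parametric`,
#'   `mask`, `aliasing` (report), `curve`, `sv` (a `stroke_volume`), and
#'   `report` (threshold used, mask pixel count, aliased fraction).
#' @export
quantify_cine_series <- function(series, roi = NULL, threshold = "otsu",
                                 background = NULL, alpha = 0.8,
                                 max_aliased_fraction = 0.1,
                                 min_aliased_pixels = 3L,
                                 correct_alias = TRUE) {
  field <- phase_to_velocity(series)
  pimg <- compute_parametric_image(field, roi)
  thr <- if (identical(threshold, "otsu")) suggest_threshold(pimg)
         else as.numeric(threshold)
  mask <- segment_by_threshold(pimg, thr)
  aliasing <- detect_aliasing(field, mask, alpha = alpha)
  if (correct_alias && aliasing$n_flagged > 0)
    field <- correct_aliasing(field, aliasing,
                              max_fraction = max_aliased_fraction,
                              min_pixels = min_aliased_pixels)
  if (!is.null(background))
    field <- background_correct(field, background, mask = mask)
  curve <- compute_flow_curve(field, mask)
  sv <- compute_stroke_volume(curve)
  list(velocity = field, parametric = pimg, mask = mask, aliasing = aliasing,
       curve = curve, sv = sv,
       report = list(threshold = thr, n_mask_pixels = mask$n_pixels,
                     aliased_pixel_fraction = aliasing$pixel_fraction,
                     sv_ul = sv$sv_ul))
}
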