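#' Rectangular region of interest
#'
#' @param rows,cols Integer length-2 inclusive 1-based ranges.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(rows, cols) {
  stopifnot(length(rows) == 2L, length(cols) == 2L)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows[1] > rows[2] || cols[1] > cols[2] || any(c(rows, cols) < 1L))
    stop("ROI must be a non-empty 1-based rectangle")
  structure(list(rows = rows, cols = cols), class = "rect_roi")
}

check_roi_inside <- function(roi, dim2) {
  if (roi$rows[2] > dim2[1] || roi$cols[2] > dim2[2])
    stop("ROI extends outside the image (", dim2[1], "x", dim2[2], ")")
  invisible(TRUE)
}

#' Cardiac-fundamental parametric image
#'
#' For every pixel in the ROI, applies an FFT to its velocity time series
#' and takes the magnitude of the first (fundamental) harmonic. Because
#' the retrospectively gated series spans exactly one averaged cardiac
#' cycle, DFT bin 1 is the frequency of the subject's heart rate: CSF,
#' which pulses with the heart, lights up; stationary tissue and
#' non-periodic noise stay dark. The normalization is 2/N, so a pixel with
#' `v(k) = A sin(2 pi k / N + phi)` gets parametric value exactly `A`
#' (cm/s), directly comparable to a velocity threshold.
#'
#' @param field A [velocity_field()].
#' @param roi A [rect_roi()], or `NULL` for the whole image.
#' @return An object of class `parametric_image`: `values` (matrix of
#'   fundamental amplitudes, cm/s, ROI-shaped), `roi`, `img_dim`,
#'   `normalization`.
#' @export
compute_parametric_image <- function(field, roi = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$v)
  if (d[3] < 4L) stop("need at least 4 frames for a fundamental harmonic")
  if (is.null(roi)) roi <- rect_roi(c(1L, d[1]), c(1L, d[2]))
  check_roi_inside(roi, d)
  sub <- field$v[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], , drop = FALSE]
  nr <- dim(sub)[1]; nc <- dim(sub)[2]; nf <- d[3]
  # pixels as columns of an (nf x npix) matrix; fundamental = FFT row 2
  m <- t(matrix(sub, nrow = nr * nc, ncol = nf))
  bin1 <- stats::mvfft(m)[2L, ]
  amp <- matrix(2 * Mod(bin1) / nf, nr, nc)
  structure(list(values = amp, roi = roi, img_dim = d[1:2],
                 normalization = "2/N"),
            class = "parametric_image")
}

#' Threshold the parametric image into a CSF mask
#'
#' Keeps every ROI pixel whose fundamental amplitude is at or above the
#' threshold, mirroring the operator's visually selected cut between
#' weakly pulsatile tissue and strongly pulsatile CSF. No
#' connected-component or size filtering is applied by default.
#'
#' @param pimg A [parametric_image][compute_parametric_image].
#' @param threshold Non-negative amplitude threshold, cm/s.
#' @param largest_component If `TRUE`, keep only the largest 4-connected
#'   component of the mask (off by default; the reference procedure
#'   thresholds only).
#' @return An object of class `segmentation_mask`: `mask` (logical matrix
#'   over the full image grid), `threshold`, `n_pixels`, `roi`.
#' @export
segment_by_threshold <- function(pimg, threshold, largest_component = FALSE) {
  stopifnot(inherits(pimg, "parametric_image"))
  if (threshold < 0) stop("threshold must be non-negative")
  mask <- matrix(FALSE, pimg$img_dim[1], pimg$img_dim[2])
  sel <- pimg$values >= threshold
  mask[pimg$roi$rows[1]:pimg$roi$rows[2],
       pimg$roi$cols[1]:pimg$roi$cols[2]] <- sel
  if (largest_component && any(mask)) mask <- keep_largest_component(mask)
  if (!any(mask))
    warning("threshold ", threshold, " yields an empty mask")
  structure(list(mask = mask, threshold = threshold, n_pixels = sum(mask),
                 roi = pimg$roi),
            class = "segmentation_mask")
}

#' Construct a segmentation mask from a logical pixel matrix
#'
#' Low-level constructor, e.g. to use a phantom's ground-truth mask or an
#' externally drawn mask with [detect_aliasing()], [background_correct()]
#' and [compute_flow_curve()].
#'
#' @param mask Logical matrix over the image grid.
#' @param threshold Threshold annotation (may be `NA` for external masks).
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(mask, threshold = NA_real_) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, threshold = threshold, n_pixels = sum(mask),
                 roi = rect_roi(c(1L, nrow(mask)), c(1L, ncol(mask)))),
            class = "segmentation_mask")
}

# 4-connected largest component by flood fill.
keep_largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask & lab == 0L)
  while (length(idx)) {
    cur <- cur + 1L
    queue <- idx[1]
    lab[queue] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(mask)) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
    idx <- which(mask & lab == 0L)
  }
  best <- which.max(tabulate(lab[lab > 0L]))
  lab == best
}

#' Suggest a segmentation threshold by two-class separation
#'
#' Exact Otsu criterion on the parametric amplitudes: the cut maximizing
#' the between-class variance over all split points of the sorted values.
#' The returned threshold is the midpoint of the gap at the optimal split,
#' so it lies strictly between the two classes. Purely advisory —
#' [segment_by_threshold()] still takes an explicit number.
#'
#' @param pimg A [parametric_image][compute_parametric_image].
#' @return Threshold in cm/s.
#' @export
suggest_threshold <- function(pimg) {
  stopifnot(inherits(pimg, "parametric_image"))
  x <- sort(as.vector(pimg$values))
  n <- length(x)
  if (n < 2L || x[1] == x[n])
    stop("all parametric values are identical; no two-class separation exists")
  cs <- cumsum(x)
  k <- seq_len(n - 1L)
  w1 <- k / n
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  between <- w1 * (1 - w1) * (m1 - m2)^2
  valid <- x[k + 1L] > x[k]  # a cut must fall in a gap between distinct values
  between[!valid] <- -Inf
  kbest <- which.max(between)
  (x[kbest] + x[kbest + 1L]) / 2
}

#' Detect velocity-aliased samples within the CSF mask
#'
#' A sample `(pixel, frame)` is flagged as aliased when its velocity sign
#' opposes the mask's instantaneous dominant sign (the sign of the mean
#' mask velocity at that frame) while its magnitude is at least
#' `alpha * venc`. This targets single phase wraps of a coherent jet: a
#' velocity just beyond +VENC reappears just above -VENC, i.e. with large
#' magnitude and the wrong sign.
#'
#' @param field A [velocity_field()].
#' @param mask A [segmentation_mask][segment_by_threshold].
#' @param alpha Magnitude fraction of VENC above which an opposing-sign
#'   sample is considered wrapped (default 0.8).
#' @return An object of class `aliasing_report`: `flagged` (data frame
#'   with `row`, `col`, `frame`), `n_flagged`, `pixel_fraction` (fraction
#'   of mask pixels with at least one flagged frame), `dominant_sign`
#'   (per-frame), `alpha`, `n_mask`.
#' @export
detect_aliasing <- function(field, mask, alpha = 0.8) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(mask, "segmentation_mask"))
  if (!any(mask$mask)) stop("mask is empty")
  d <- dim(field$v)
  venc <- field$meta$venc
  idx <- which(mask$mask)
  nr <- d[1]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  flagged <- vector("list", d[3])
  dom <- integer(d[3])
  for (k in seq_len(d[3])) {
    vk <- field$v[, , k][idx]
    dom[k] <- sign(mean(vk))
    if (dom[k] == 0) next
    hit <- sign(vk) == -dom[k] & abs(vk) >= alpha * venc
    if (any(hit))
      flagged[[k]] <- data.frame(row = rows[hit], col = cols[hit], frame = k)
  }
  flagged <- do.call(rbind, c(flagged,
                              list(data.frame(row = integer(0), col = integer(0),
                                              frame = integer(0)))))
  structure(list(flagged = flagged, n_flagged = nrow(flagged),
                 pixel_fraction = length(unique(flagged$row +
                                                  nr * flagged$col)) / length(idx),
                 dominant_sign = dom, alpha = alpha, n_mask = length(idx)),
            class = "aliasing_report")
}

#' Correct single-wrap velocity aliasing
#'
#' Each flagged sample is shifted by `2 * venc` toward the mask's
#' dominant sign at its frame, undoing a single phase wrap. If more than
#' "a few" mask pixels are affected — more than `max_fraction` of them
#' and more than `min_pixels` in absolute count — correction is refused:
#' too much of the region is wrapped for postprocessing, and the
#' acquisition should be repeated with twice the previous VENC. The
#' absolute floor keeps the percentage policy meaningful for very small
#' masks (an aqueductal jet may be under ten pixels, where one wrapped
#' pixel already exceeds 10%).
#'
#' @param field A [velocity_field()].
#' @param report An [aliasing_report][detect_aliasing].
#' @param max_fraction Largest tolerated fraction of affected mask pixels
#'   (default 0.1).
#' @param min_pixels Affected-pixel count always tolerated regardless of
#'   fraction (default 3).
#' @return The corrected `velocity_field` with `aliasing_corrected = TRUE`.
#' @export
correct_aliasing <- function(field, report, max_fraction = 0.1,
                             min_pixels = 3L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(report, "aliasing_report"))
  n_affected <- round(report$pixel_fraction * report$n_mask)
  if (n_affected > max(min_pixels, max_fraction * report$n_mask))
    stop(sprintf(paste0("aliasing affects %.0f%% of mask pixels ",
                        "(policy limit %.0f%%); too many pixels require ",
                        "aliasing correction - the acquisition should be ",
                        "repeated with twice the previous VENC"),
                 100 * report$pixel_fraction, 100 * max_fraction))
  v <- field$v
  if (report$n_flagged > 0) {
    fl <- report$flagged
    venc <- field$meta$venc
    shift <- 2 * venc * report$dominant_sign[fl$frame]
    v[cbind(fl$row, fl$col, fl$frame)] <-
      v[cbind(fl$row, fl$col, fl$frame)] + shift
  }
  velocity_field(v, field$meta, aliasing_corrected = TRUE,
                 background_corrected = field$background_corrected)
}
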