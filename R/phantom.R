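#' Define a pulsatile flow region for the synthetic phantom
#'
#' A region is a disc (aqueduct-like jet) or an annulus (cervical
#' subarachnoid-space-like crown) of pixels carrying a pulsatile velocity
#' waveform. The velocity at pixel \eqn{(r,c)} and time \eqn{t} is
#' \deqn{v(r,c,t) = v_{peak} \, s(r,c) \, w(t)}
#' where \eqn{s} is the spatial profile (1 at the profile peak, 0 at the
#' region boundary for `"parabolic"`; identically 1 for `"flat"`) and
#' \eqn{w(t)} is a dimensionless truncated Fourier series in cardiac phase,
#' \deqn{w(t) = c_0 + \sum_h A_h \sin(2\pi h t/T + \phi_h).}
#'
#' @param geometry `"disc"` or `"annulus"`.
#' @param center Numeric length-2, `(row, col)` pixel coordinates of the
#'   region center.
#' @param radius Disc radius in pixels (disc geometry only).
#' @param radii Numeric length-2, inner and outer radii in pixels
#'   (annulus geometry only); inner must be smaller than outer.
#' @param profile Spatial profile, `"parabolic"` (Poiseuille-like) or
#'   `"flat"`.
#' @param peak_velocity Velocity scale in cm/s: the peak spatio-temporal
#'   velocity for a unit-amplitude pure-fundamental waveform.
#' @param waveform List with elements `amplitudes` (per-harmonic sine
#'   amplitudes, dimensionless), `phases` (radians, recycled to the length
#'   of `amplitudes`) and `constant` (dimensionless net-flow term).
#' @return An object of class `region_spec`.
#' @seealso [phantom_spec()], [generate_cine_series()]
#' @export
region_spec <- function(geometry = c("disc", "annulus"),
                        center,
                        radius = NULL,
                        radii = NULL,
                        profile = c("parabolic", "flat"),
                        peak_velocity,
                        waveform = list(amplitudes = 1, phases = 0, constant = 0)) {
  geometry <- match.arg(geometry)
  profile <- match.arg(profile)
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(peak_velocity), length(peak_velocity) == 1L)
  if (geometry == "disc") {
    if (is.null(radius) || radius <= 0)
      stop("disc region requires a positive 'radius'")
  } else {
    if (is.null(radii) || length(radii) != 2L || any(radii <= 0))
      stop("annulus region requires positive 'radii' = c(inner, outer)")
    if (radii[1] >= radii[2])
      stop("annulus inner radius must be smaller than the outer radius")
  }
  waveform <- validate_waveform(waveform)
  pulsatile <- any(waveform$amplitudes != 0)
  if (!pulsatile && waveform$constant == 0)
    stop("region waveform must have at least one nonzero harmonic or constant term")
  structure(list(geometry = geometry, center = as.numeric(center),
                 radius = radius, radii = radii, profile = profile,
                 peak_velocity = peak_velocity, waveform = waveform),
            class = "region_spec")
}

validate_waveform <- function(w) {
  if (!is.list(w)) stop("waveform must be a list")
  amplitudes <- w$amplitudes %||% numeric(0)
  phases <- rep_len(w$phases %||% 0, length(amplitudes))
  constant <- w$constant %||% 0
  stopifnot(is.numeric(amplitudes), is.numeric(phases),
            is.numeric(constant), length(constant) == 1L)
  list(amplitudes = amplitudes, phases = phases, constant = constant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate the dimensionless waveform at times t (seconds) for cycle T.
eval_waveform <- function(waveform, t, cycle_duration) {
  w <- rep(waveform$constant, length(t))
  for (h in seq_along(waveform$amplitudes)) {
    w <- w + waveform$amplitudes[h] *
      sin(2 * pi * h * t / cycle_duration + waveform$phases[h])
  }
  w
}

# Spatial profile sampled at pixel centers; returns a matrix of s(r,c),
# zero outside the region. Membership: disc d < r; annulus inner <= d < outer.
region_profile <- function(region, grid_shape) {
  r <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  c <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  d <- sqrt((r - region$center[1])^2 + (c - region$center[2])^2)
  if (region$geometry == "disc") {
    inside <- d < region$radius
    s <- if (region$profile == "parabolic") 1 - (d / region$radius)^2 else 1
  } else {
    inner <- region$radii[1]; outer <- region$radii[2]
    inside <- d >= inner & d < outer
    if (region$profile == "parabolic") {
      mid <- (inner + outer) / 2
      half <- (outer - inner) / 2
      s <- 1 - ((d - mid) / half)^2
    } else s <- 1
  }
  out <- matrix(0, grid_shape[1], grid_shape[2])
  out[inside] <- (s * inside)[inside]
  out
}

#' Specify a synthetic cine phase-contrast acquisition
#'
#' Collects the geometry, timing, velocity-encoding and artefact parameters
#' for [generate_cine_series()]. Defaults mirror a single-slice cardiac-gated
#' acquisition reconstructed to 32 frames over one averaged cardiac cycle.
#'
#' @param grid_shape Integer length-2, image rows and columns.
#' @param pixel_spacing Pixel edge length in mm.
#' @param n_frames Number of reconstructed cardiac frames (>= 4).
#' @param cycle_duration Cardiac (RR) cycle duration in seconds.
#' @param regions List of [region_spec()] objects (may be empty).
#' @param noise_sd Standard deviation of i.i.d. Gaussian velocity noise,
#'   cm/s, added per pixel per frame.
#' @param eddy_gradient Numeric length-3 `(e0, er, ec)`: a planar
#'   eddy-current velocity offset `e0 + er*row + ec*col` cm/s (1-based
#'   pixel indices) added to every frame.
#' @param venc Velocity-encoding limit in cm/s.
#' @param apply_wrap If `TRUE`, velocities beyond `venc` are phase-wrapped
#'   into `[-venc, venc)` in the emitted series, as a phase measurement
#'   would do; if `FALSE`, any out-of-range velocity is an error.
#' @param seed Integer seed; identical seeds give identical output.
#' @param site_label Site annotation carried in the metadata.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L),
                         pixel_spacing = 0.55,
                         n_frames = 32L,
                         cycle_duration = 1.0,
                         regions = list(),
                         noise_sd = 0,
                         eddy_gradient = c(0, 0, 0),
                         venc = 10,
                         apply_wrap = TRUE,
                         seed = 1L,
                         site_label = "aqueduct") {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1))
  if (n_frames < 4L) stop("n_frames must be at least 4")
  if (cycle_duration <= 0) stop("cycle_duration must be positive")
  if (venc <= 0) stop("venc must be positive")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(length(eddy_gradient) == 3L)
  if (!all(vapply(regions, inherits, logical(1), "region_spec")))
    stop("'regions' must be a list of region_spec objects")
  structure(list(grid_shape = as.integer(grid_shape),
                 pixel_spacing = pixel_spacing, n_frames = as.integer(n_frames),
                 cycle_duration = cycle_duration, regions = regions,
                 noise_sd = noise_sd, eddy_gradient = as.numeric(eddy_gradient),
                 venc = venc, apply_wrap = isTRUE(apply_wrap),
                 seed = as.integer(seed), site_label = site_label),
            class = "phantom_spec")
}

#' Default aqueduct and cervical phantom specifications
#'
#' `aqueduct_phantom()` is a small high-velocity jet: a parabolic disc of
#' radius 2 px (0.55 mm pixels), peak 10 cm/s, VENC 10 cm/s, pure
#' fundamental waveform over a 1 s cycle. `cervical_phantom()` is an
#' annular region (inner 6, outer 9 px) with a flat 4.3 cm/s profile at
#' VENC 5 cm/s; its true stroke volume is roughly ten times the
#' aqueductal one, matching the physiological ratio between cervical and
#' aqueductal CSF pulsatility.
#'
#' @param noise_sd Gaussian velocity-noise SD, cm/s.
#' @param eddy_gradient Planar eddy offset `(e0, er, ec)`, cm/s.
#' @param seed Integer seed.
#' @param venc Velocity-encoding limit, cm/s.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
aqueduct_phantom <- function(noise_sd = 0, eddy_gradient = c(0, 0, 0),
                             seed = 1L, venc = 10, ...) {
  phantom_spec(regions = list(region_spec("disc", center = c(33, 33), radius = 2,
                                          profile = "parabolic", peak_velocity = 10)),
               noise_sd = noise_sd, eddy_gradient = eddy_gradient,
               venc = venc, seed = seed, site_label = "aqueduct", ...)
}

#' @rdname aqueduct_phantom
#' @export
cervical_phantom <- function(noise_sd = 0, eddy_gradient = c(0, 0, 0),
                             seed = 1L, venc = 5, ...) {
  phantom_spec(regions = list(region_spec("annulus", center = c(33, 33),
                                          radii = c(6, 9), profile = "flat",
                                          peak_velocity = 4.3)),
               noise_sd = noise_sd, eddy_gradient = eddy_gradient,
               venc = venc, seed = seed, site_label = "cervical", ...)
}

#' Wrap a velocity into the VENC-representable range
#'
#' Phase-contrast velocity encoding maps velocity linearly to phase, so a
#' true velocity outside `[-venc, venc)` aliases onto
#' `((v + venc) mod 2 venc) - venc`. Velocities already in range are
#' returned unchanged (bit-identical).
#'
#' @param v_true Numeric vector/array of true velocities, cm/s.
#' @param venc Velocity-encoding limit, cm/s (> 0).
#' @return Wrapped velocities in `[-venc, venc)`, same shape as `v_true`.
#' @examples
#' wrap_phase(4, 10)    # 4  (in range)
#' wrap_phase(12, 10)   # -8
#' wrap_phase(-12, 10)  # 8
#' @export
wrap_phase <- function(v_true, venc) {
  if (venc <= 0) stop("venc must be positive")
  out <- v_true
  oob <- v_true < -venc | v_true >= venc
  out[oob] <- ((v_true[oob] + venc) %% (2 * venc)) - venc
  out
}

#' Generate a synthetic cine phase-contrast series with known ground truth
#'
#' Builds the velocity truth as the sum of region velocities, a planar
#' eddy-current offset and i.i.d. Gaussian noise, sampled at pixel centers
#' and at frame times `k*T/N` (`k = 0..N-1`); phase-wraps it if requested;
#' and encodes it into a stored-phase stack under the linear VENC
#' convention. The returned ground truth carries, per region, the analytic
#' flow curve, the true stroke volume (from a dense quadrature of the
#' continuous waveform) and the true pixel mask, plus the full pre-wrap
#' velocity field, the eddy field and the wrap log.
#'
#' @param spec A [phantom_spec()].
#' @param allow_double_wrap If `FALSE` (default), a region peak velocity
#'   at or beyond `2*venc` with wrapping enabled is rejected, because a
#'   double wrap cannot be undone by single-wrap aliasing correction.
#' @return A list with elements `series` (a [cine_series][read_cine]) and
#'   `truth` (class `ground_truth`): `regions` (each with `mask`,
#'   `curve_ml_s`, `sv_ul`), `velocity` (pre-wrap field, cm/s), `eddy`
#'   (matrix, cm/s), `wrap` (logical array of wrapped samples) and
#'   `n_wrapped`.
#' @export
generate_cine_series <- function(spec, allow_double_wrap = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  n <- spec$n_frames
  tk <- (seq_len(n) - 1) * spec$cycle_duration / n
  area_mm2 <- spec$pixel_spacing^2

  # region velocities, analytic truth
  v <- array(0, dim = c(gs[1], gs[2], n))
  truth_regions <- vector("list", length(spec$regions))
  for (i in seq_along(spec$regions)) {
    reg <- spec$regions[[i]]
    check_region_inside(reg, gs)
    if (spec$apply_wrap && !allow_double_wrap && reg$peak_velocity >= 2 * spec$venc)
      stop("region peak velocity >= 2*venc would double-wrap irrecoverably; ",
           "increase venc or set allow_double_wrap = TRUE")
    s <- region_profile(reg, gs)
    w <- eval_waveform(reg$waveform, tk, spec$cycle_duration)
    for (k in seq_len(n)) v[, , k] <- v[, , k] + reg$peak_velocity * s * w[k]
    # analytic flow curve (mL/s) and dense-quadrature stroke volume (uL)
    scale_ml <- 0.01 * reg$peak_velocity * sum(s) * area_mm2
    curve <- scale_ml * w
    nfine <- 32768L
    tf <- (seq_len(nfine) - 1) * spec$cycle_duration / nfine
    wf <- eval_waveform(reg$waveform, tf, spec$cycle_duration)
    sv_ul <- 1000 * 0.5 * mean(abs(scale_ml * wf)) * spec$cycle_duration
    truth_regions[[i]] <- list(mask = s > 0, curve_ml_s = curve, sv_ul = sv_ul)
  }

  eddy <- outer(seq_len(gs[1]), seq_len(gs[2]),
                function(r, c) spec$eddy_gradient[1] +
                  spec$eddy_gradient[2] * r + spec$eddy_gradient[3] * c)
  if (any(spec$eddy_gradient != 0))
    for (k in seq_len(n)) v[, , k] <- v[, , k] + eddy

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    v <- v + array(stats::rnorm(length(v), sd = spec$noise_sd), dim = dim(v))
  }

  if (spec$apply_wrap) {
    # encode on the closed interval: exactly +venc is representable at the
    # top of the stored phase range, so only |v| > venc truly wraps
    v_emit <- v
    oob <- abs(v) > spec$venc
    v_emit[oob] <- wrap_phase(v[oob], spec$venc)
    wrap <- v_emit != v
  } else {
    if (any(abs(v) > spec$venc))
      stop("velocities exceed venc with apply_wrap = FALSE; ",
           "enable wrapping or increase venc")
    v_emit <- v
    wrap <- array(FALSE, dim = dim(v))
  }

  meta <- acquisition_meta(venc = spec$venc, pixel_spacing = spec$pixel_spacing,
                           n_frames = n, cycle_duration = spec$cycle_duration,
                           site_label = spec$site_label, seed = spec$seed)
  series <- cine_series(velocity_to_phase(v_emit, meta), meta)
  truth <- structure(list(regions = truth_regions, velocity = v, eddy = eddy,
                          wrap = wrap, n_wrapped = sum(wrap)),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

check_region_inside <- function(reg, grid_shape) {
  r_out <- if (reg$geometry == "disc") reg$radius else reg$radii[2]
  lo <- reg$center - r_out
  hi <- reg$center + r_out
  if (any(lo < 1) || hi[1] > grid_shape[1] || hi[2] > grid_shape[2])
    stop("region extends outside the image grid (center ",
         paste(reg$center, collapse = ","), ", outer radius ", r_out, ")")
  invisible(TRUE)
}

#' Specify a synthetic three-timepoint stroke-volume cohort
#'
#' Marginal means/SDs default to the preoperative, 6-month and 12-month
#' levels of a 14-patient shunted normal-pressure-hydrocephalus cohort:
#' aqueductal stroke volume 240/214/193 uL per cycle (SD 114/157/145) and
#' cervical stroke volume 627/557/496 uL (SD 229/234/234). Draws are
#' log-normal, moment-matched to the requested mean/SD, with a shared
#' per-patient factor inducing the across-timepoint correlation; a stated
#' fraction of "non-responder" patients has its patient-level log-change
#' from baseline sign-flipped, so their stroke volumes increase after
#' surgery.
#'
#' @param n_patients Number of patients.
#' @param sv_aqu_mean,sv_aqu_sd Length-3 mean and SD (uL/cycle) of
#'   aqueductal stroke volume at T1 (preop), T2 (6 mo), T3 (12 mo).
#' @param sv_cerv_mean,sv_cerv_sd Same for cervical stroke volume.
#' @param correlation Within-patient correlation of the latent normal
#'   scores across timepoints, in `[0, 1)`.
#' @param nonresponder_fraction Fraction of patients whose postoperative
#'   change is sign-flipped (default 2/14, the observed minority of
#'   patients whose stroke volume rose after shunting).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 14L,
                        sv_aqu_mean = c(240, 214, 193),
                        sv_aqu_sd = c(114, 157, 145),
                        sv_cerv_mean = c(627, 557, 496),
                        sv_cerv_sd = c(229, 234, 234),
                        correlation = 0.6,
                        nonresponder_fraction = 2 / 14,
                        seed = 1L) {
  stopifnot(n_patients >= 0, length(sv_aqu_mean) == 3L, length(sv_aqu_sd) == 3L,
            length(sv_cerv_mean) == 3L, length(sv_cerv_sd) == 3L)
  if (any(c(sv_aqu_mean, sv_cerv_mean) <= 0)) stop("means must be positive")
  if (any(c(sv_aqu_sd, sv_cerv_sd) < 0)) stop("SDs must be non-negative")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1); a perfectly (or over-) correlated ",
         "cohort is infeasible in this model")
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1)
    stop("nonresponder_fraction must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 sv_aqu_mean = sv_aqu_mean, sv_aqu_sd = sv_aqu_sd,
                 sv_cerv_mean = sv_cerv_mean, sv_cerv_sd = sv_cerv_sd,
                 correlation = correlation,
                 nonresponder_fraction = nonresponder_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic paired three-timepoint cohort
#'
#' @param spec A [cohort_spec()].
#' @return A long-format data frame with columns `patient_id`, `timepoint`
#'   (`"T1"`, `"T2"`, `"T3"`), `sv_aqu_ul`, `sv_cerv_ul`. Identical seeds
#'   give identical tables.
#' @details Log-normal parameters are moment-matched:
#'   \eqn{\sigma^2 = \log(1 + SD^2/M^2)}, \eqn{\mu = \log M - \sigma^2/2},
#'   so the marginal mean and SD equal the specification exactly; an SD of
#'   zero collapses the draw to the mean. The latent score at timepoint t is
#'   \eqn{Z_t = \sqrt{\rho}\,U + \sqrt{1-\rho}\,\epsilon_t} with a shared
#'   patient factor U.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients
  if (np == 0L)
    return(data.frame(patient_id = character(0), timepoint = character(0),
                      sv_aqu_ul = numeric(0), sv_cerv_ul = numeric(0)))
  set.seed(spec$seed)
  rho <- spec$correlation
  n_flip <- round(spec$nonresponder_fraction * np)
  flip <- sample(seq_len(np), n_flip)

  draw_measure <- function(means, sds) {
    sigma <- sqrt(log(1 + (sds / means)^2))
    mu <- log(means) - sigma^2 / 2
    u <- stats::rnorm(np)
    logx <- matrix(0, np, 3)
    for (t in 1:3) {
      z <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(np)
      logx[, t] <- mu[t] + sigma[t] * z
    }
    # sign-flip the patient-level log-change from baseline for non-responders
    for (t in 2:3) logx[flip, t] <- 2 * logx[flip, 1] - logx[flip, t]
    exp(logx)
  }

  aqu <- draw_measure(spec$sv_aqu_mean, spec$sv_aqu_sd)
  cerv <- draw_measure(spec$sv_cerv_mean, spec$sv_cerv_sd)
  ids <- sprintf("P%02d", seq_len(np))
  data.frame(patient_id = rep(ids, each = 3),
             timepoint = rep(c("T1", "T2", "T3"), np),
             sv_aqu_ul = as.vector(t(aqu)),
             sv_cerv_ul = as.vector(t(cerv)))
}
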