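make_field <- function(v, venc = 10, pixel_spacing = 0.55, cycle = 1) {
  meta <- acquisition_meta(venc = venc, pixel_spacing = pixel_spacing,
                           n_frames = dim(v)[3], cycle_duration = cycle)
  velocity_field(v, meta)
}

test_that("parametric image recovers sine amplitude, ignores DC and higher harmonics", {
  n <- 32
  k <- 0:(n - 1)
  v <- array(0, dim = c(2, 2, n))
  v[1, 1, ] <- 3 * sin(2 * pi * k / n)          # pure fundamental, A = 3
  v[1, 2, ] <- 7.5                              # temporally constant
  v[2, 1, ] <- 2 * sin(4 * pi * k / n)          # pure 2nd harmonic
  v[2, 2, ] <- 3 * sin(2 * pi * k / n + 0.9) - 4  # fundamental + DC offset
  p <- compute_parametric_image(make_field(v))
  expect_equal(p$values[1, 1], 3, tolerance = 1e-12)
  expect_equal(p$values[1, 2], 0, tolerance = 1e-12)
  expect_equal(p$values[2, 1], 0, tolerance = 1e-12)
  expect_equal(p$values[2, 2], 3, tolerance = 1e-12)
})

test_that("parametric image equals the direct-summation DFT oracle and is linear", {
  set.seed(21)
  v <- array(rnorm(16 * 16 * 32), dim = c(16, 16, 32))
  p <- compute_parametric_image(make_field(v))
  expect_equal(p$values, oracle_dft_bin1(v), tolerance = 1e-10)
  # linearity in velocity scaling
  p4 <- compute_parametric_image(make_field(4 * v))
  expect_equal(p4$values, 4 * p$values, tolerance = 1e-10)
  # DC insensitivity: adding any constant per pixel leaves amplitudes unchanged
  offs <- matrix(rnorm(16 * 16, sd = 5), 16, 16)
  vdc <- v + array(rep(offs, 32), dim = dim(v))
  pdc <- compute_parametric_image(make_field(vdc))
  expect_equal(pdc$values, p$values, tolerance = 1e-10)
})

test_that("parametric image respects the ROI and validates it", {
  set.seed(4)
  v <- array(rnorm(10 * 12 * 8), dim = c(10, 12, 8))
  roi <- rect_roi(c(3, 6), c(2, 9))
  p <- compute_parametric_image(make_field(v), roi)
  full <- compute_parametric_image(make_field(v))
  expect_equal(p$values, full$values[3:6, 2:9], tolerance = 1e-12)
  expect_error(compute_parametric_image(make_field(v), rect_roi(c(3, 11), c(1, 2))),
               "outside")
  expect_error(rect_roi(c(5, 3), c(1, 2)), "non-empty")
})

test_that("thresholding keeps exactly the pixels at or above the threshold", {
  n <- 32; k <- 0:(n - 1)
  v <- array(0, dim = c(1, 2, n))
  v[1, 1, ] <- 3 * sin(2 * pi * k / n)
  v[1, 2, ] <- 0.05 * sin(2 * pi * k / n)
  p <- compute_parametric_image(make_field(v))
  m <- segment_by_threshold(p, 1.0)
  expect_identical(as.vector(m$mask), c(TRUE, FALSE))
  expect_equal(m$n_pixels, 1)
  m0 <- segment_by_threshold(p, 0)
  expect_true(all(m0$mask))
  expect_warning(segment_by_threshold(p, 100), "empty mask")
})

test_that("noise-free phantom segmentation recovers the ground-truth mask exactly", {
  g <- generate_cine_series(aqueduct_phantom())
  f <- phase_to_velocity(g$series)
  p <- compute_parametric_image(f)
  # any threshold between 0 and the smallest in-mask amplitude works; the
  # boundary-adjacent amplitude is peak * s at the innermost excluded ring
  for (thr in c(0.5, 1.0, 2.0)) {
    m <- segment_by_threshold(p, thr)
    expect_identical(m$mask, g$truth$regions[[1]]$mask)
  }
})

test_that("suggested threshold separates tissue from CSF and recovers the mask", {
  g <- generate_cine_series(aqueduct_phantom(noise_sd = 0.3, seed = 5))
  f <- phase_to_velocity(g$series)
  p <- compute_parametric_image(f)
  thr <- suggest_threshold(p)
  # strictly between the noise mode and the smallest CSF amplitude (5 cm/s)
  expect_gt(thr, max(p$values[!g$truth$regions[[1]]$mask]) * 0.99)
  expect_lt(thr, 5)
  m <- segment_by_threshold(p, thr)
  expect_identical(m$mask, g$truth$regions[[1]]$mask)
  # identical values have no two-class separation
  flatp <- structure(list(values = matrix(1, 3, 3), roi = rect_roi(c(1, 3), c(1, 3)),
                          img_dim = c(3L, 3L), normalization = "2/N"),
                     class = "parametric_image")
  expect_error(suggest_threshold(flatp), "identical")
})

test_that("aliasing detection is empty on wrap-free and uniformly signed fields", {
  g <- generate_cine_series(aqueduct_phantom())
  f <- phase_to_velocity(g$series)
  m <- segmentation_mask(g$truth$regions[[1]]$mask)
  rep0 <- detect_aliasing(f, m)
  expect_equal(rep0$n_flagged, 0)
  expect_equal(rep0$pixel_fraction, 0)
  # uniformly positive field: high magnitudes but no sign opposition
  v <- array(9.5, dim = c(8, 8, 8))
  mpos <- segmentation_mask(matrix(TRUE, 8, 8))
  expect_equal(detect_aliasing(make_field(v), mpos)$n_flagged, 0)
})

test_that("flagged samples equal the generator wrap log for a supra-VENC jet", {
  spec <- phantom_spec(regions = list(region_spec("disc", c(33, 33), radius = 2,
                                                  profile = "parabolic",
                                                  peak_velocity = 12)),
                       venc = 10, seed = 3)
  g <- generate_cine_series(spec)
  f <- phase_to_velocity(g$series)
  m <- segmentation_mask(g$truth$regions[[1]]$mask)
  rep <- detect_aliasing(f, m)
  wl <- which(g$truth$wrap, arr.ind = TRUE)
  expect_gt(nrow(wl), 0)
  expect_setequal(paste(rep$flagged$row, rep$flagged$col, rep$flagged$frame),
                  paste(wl[, 1], wl[, 2], wl[, 3]))
})

test_that("aliasing correction undoes single wraps and is identity on empty flags", {
  spec <- phantom_spec(regions = list(region_spec("disc", c(33, 33), radius = 2,
                                                  profile = "parabolic",
                                                  peak_velocity = 12)),
                       venc = 10, seed = 3)
  g <- generate_cine_series(spec)
  f <- phase_to_velocity(g$series)
  m <- segmentation_mask(g$truth$regions[[1]]$mask)
  rep <- detect_aliasing(f, m)
  fc <- correct_aliasing(f, rep)
  expect_true(fc$aliasing_corrected)
  expect_equal(fc$v, g$truth$velocity, tolerance = 1e-9)
  # empty flagged set: field unchanged
  g0 <- generate_cine_series(aqueduct_phantom())
  f0 <- phase_to_velocity(g0$series)
  rep0 <- detect_aliasing(f0, segmentation_mask(g0$truth$regions[[1]]$mask))
  expect_equal(correct_aliasing(f0, rep0)$v, f0$v, tolerance = 0)
})

test_that("correction is refused when more than a few mask pixels are wrapped", {
  # 32-pixel mask, half of it flagged: far beyond both the 10% fraction and
  # the 3-pixel absolute floor
  n <- 8
  v <- array(0, dim = c(8, 8, n))
  mask <- matrix(FALSE, 8, 8); mask[1:4, 1:8] <- TRUE
  v[1:2, 1:8, ] <- -9.5  # opposes dominant sign at high magnitude
  v[3:4, 1:8, ] <- 9.9
  v[5:8, , ] <- 0.1
  f <- make_field(v)
  rep <- detect_aliasing(f, segmentation_mask(mask))
  expect_equal(rep$pixel_fraction, 0.5)
  expect_error(correct_aliasing(f, rep), "twice the previous VENC")
})

test_that("largest-component filtering is available but off by default", {
  n <- 32; k <- 0:(n - 1)
  v <- array(0, dim = c(6, 6, n))
  for (px in list(c(1, 1), c(1, 2), c(2, 1), c(5, 5)))
    v[px[1], px[2], ] <- 3 * sin(2 * pi * k / n)
  p <- compute_parametric_image(make_field(v))
  m <- segment_by_threshold(p, 1)
  expect_equal(m$n_pixels, 4)
  mlc <- segment_by_threshold(p, 1, largest_component = TRUE)
  expect_equal(mlc$n_pixels, 3)
  expect_false(mlc$mask[5, 5])
})
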