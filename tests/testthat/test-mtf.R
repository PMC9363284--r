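# Edge-method MTF chain: edge fitting, ESF sampling, LSF differentiation,
# normalized Fourier transform, percentile readout.

# analytic ESF curve (values sampled from a closed form, no imaging)
analytic_esf <- function(fun, h = 0.02, half = 6, pixel_mm = 0.2) {
  x <- seq(-half, half, by = h)
  phantomqc:::new_esf_curve(tibble::tibble(x = x, value = fun(x),
                                           n = rep(1L, length(x))),
                            h, pixel_mm)
}

test_that("edge detection recovers angle and polarity, rejects flat ROIs", {
  g0 <- phantom_slanted_edge(0, c(20, 20))
  v0 <- rasterize_phantom(g0, 0.4, n_slices = 1, grid_mm = c(20, 20))
  e0 <- detect_edge(v0, roi_rect(c(0, 0), 16, 16))
  expect_lt(abs(e0$angle_deg), 0.1)
  expect_equal(e0$polarity, 1)

  g3 <- phantom_slanted_edge(3, c(20, 20))
  v3 <- rasterize_phantom(g3, 0.4, n_slices = 1, grid_mm = c(20, 20))
  e3 <- detect_edge(v3, roi_rect(c(0, 0), 16, 16))
  expect_lt(abs(e3$angle_deg - 3), 0.2)
  expect_lt(e3$residual_rms_px, 1)

  flat <- volume_image(array(100, c(50, 50, 1)), 0.4)
  expect_error(detect_edge(flat, roi_rect(c(0, 0), 16, 16)),
               class = "phantomqc_no_edge")
})

test_that("ESF of a blurred edge matches the Gaussian CDF at every bin", {
  fwhm <- 1.0
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  g <- phantom_slanted_edge(3, c(24, 24), 0, 1000)
  model <- acquisition_model(blur_fwhm = fwhm, noise_sd_ref = 0,
                             cupping_amplitude = 0, voxel_size = 0.2)
  vol <- simulate_acquisition(g, model, protocol_meta("T", 1, 0.2),
                              n_slices = 1, window = list(center = c(0, 0),
                                                          size = c(24, 24)))
  edge <- detect_edge(vol, roi_rect(c(0, 0), 18, 18))
  esf <- sample_esf(vol, edge)
  ## closed form: plateau difference x Gaussian CDF (aperture adds < 1%
  ## of the plateau at 0.2 mm pixels)
  ref <- 1000 * pnorm(esf$x / sig)
  keep <- abs(esf$x) <= 4
  expect_lt(max(abs(esf$value[keep] - ref[keep])), 0.01 * 1000)
  ## plateau levels equal the two materials' HU
  expect_lt(abs(mean(esf$value[esf$x > 3 & esf$x < 6]) - 1000), 2)
  expect_lt(abs(mean(esf$value[esf$x < -3 & esf$x > -6])), 2)
})

test_that("LSF differentiation: step, Gaussian CDF and ramp behave as derivatives", {
  ## unit step: derivative mass 1 concentrated at the step
  step <- analytic_esf(function(x) as.numeric(x >= 0))
  lsf <- differentiate_to_lsf(step)
  h <- attr(lsf, "bin_width_mm")
  expect_equal(sum(lsf$value) * h, 1, tolerance = 1e-9)
  expect_lte(sum(lsf$value > 0), 2)          # central difference: <= 2 bins
  expect_lt(max(abs(lsf$x[lsf$value > 0])), 2 * h)

  ## Gaussian CDF -> Gaussian PDF, within 2% of the peak before windowing
  sig <- 0.425
  cdf <- analytic_esf(function(x) pnorm(x / sig))
  lg <- differentiate_to_lsf(cdf)
  ref <- dnorm(lg$x / sig) / sig
  expect_lt(max(abs(lg$value - ref)), 0.02 * max(ref))

  ## linear ramp -> constant derivative (before windowing)
  ramp <- analytic_esf(function(x) 3 * x)
  lr <- differentiate_to_lsf(ramp)
  expect_equal(unname(lr$value), rep(3, nrow(lr)), tolerance = 1e-9)
})

test_that("normalized transform: MTF(0)=1 exactly, Gaussian pair, polarity", {
  sig <- 0.5
  cdf <- analytic_esf(function(x) pnorm(x / sig), half = 8)
  ## a wide window (the factor is a tunable): the default 4x FWQM window
  ## biases a pure-Gaussian spectrum by ~2% on its own
  lsf <- differentiate_to_lsf(cdf, window_factor = 8)
  curve <- lsf_to_mtf(lsf, f_max = 1.0)
  expect_identical(curve$modulation[1], 1)
  ref <- exp(-2 * pi^2 * sig^2 * curve$frequency^2)
  expect_lt(max(abs(curve$modulation - ref)), 0.02)
  ## mirror-image edge gives the identical MTF (modulus kills the sign)
  cdf2 <- analytic_esf(function(x) pnorm(-x / sig), half = 8)
  curve2 <- lsf_to_mtf(differentiate_to_lsf(cdf2, window_factor = 8), f_max = 1.0)
  expect_equal(curve2$modulation, curve$modulation, tolerance = 1e-9)
  ## zero-area LSF is undefined
  flat <- analytic_esf(function(x) rep(0, length(x)))
  expect_error(lsf_to_mtf(differentiate_to_lsf(flat)),
               class = "phantomqc_zero_lsf")
})

test_that("percentile readout interpolates and never extrapolates", {
  mk <- function(f, m) phantomqc:::new_mtf_curve(
    tibble::tibble(frequency = f, modulation = m), NA, NA, max(f), 0.4,
    0.04)
  expect_equal(mtf_percentile(mk(c(0, 0.65), c(1, 0.5)), 0.5), 0.65)
  expect_equal(mtf_percentile(mk(c(0, 1, 2), c(1, 0.6, 0.2)), 0.4), 1.5)
  expect_warning(out <- mtf_percentile(mk(c(0, 1), c(1, 0.8)), 0.5),
                 "beyond Nyquist")
  expect_true(is.na(out))
  ## closed-form Gaussian MTF: both percentiles to within 3%
  sig <- 0.5
  curve <- lsf_to_mtf(differentiate_to_lsf(
    analytic_esf(function(x) pnorm(x / sig), half = 8), window_factor = 8),
    f_max = 1.2)
  expect_equal(mtf_percentile(curve, 0.5), sqrt(log(2) / (2 * pi^2 * sig^2)),
               tolerance = 0.03)
  expect_equal(mtf_percentile(curve, 0.1), sqrt(log(10) / (2 * pi^2 * sig^2)),
               tolerance = 0.03)
})

test_that("end-to-end rim measurement recovers the simulated blur", {
  gu <- phantom_uniformity()
  m0 <- acquisition_model(blur_fwhm = 0.59, noise_sd_ref = 0,
                          cupping_amplitude = 0, voxel_size = 0.2)
  v0 <- simulate_acquisition(gu, m0, protocol_meta("T", 1, 0.2), n_slices = 1,
                             window = list(center = c(66, 0), size = c(22, 24)))
  mt <- measure_mtf(v0, roi_rect(c(68, 0), 10, 20), circle_center = c(0, 0))
  sig <- 0.59 / (2 * sqrt(2 * log(2)))
  expect_equal(attr(mt, "mtf50"), sqrt(log(2) / (2 * pi^2 * sig^2)),
               tolerance = 0.05)
  ## with noise, the mean over 10 seeds stays within 10% of the truth
  mn <- acquisition_model(blur_fwhm = 0.59, noise_sd_ref = 20,
                          cupping_amplitude = 0, voxel_size = 0.2)
  f50 <- vapply(1:10, function(s) {
    v <- simulate_acquisition(gu, mn, protocol_meta("T", 1, 0.2), n_slices = 1,
                              seed = 700 + s,
                              window = list(center = c(66, 0), size = c(22, 24)))
    attr(measure_mtf(v, roi_rect(c(68, 0), 10, 20), circle_center = c(0, 0)),
         "mtf50")
  }, numeric(1))
  expect_equal(mean(f50), sqrt(log(2) / (2 * pi^2 * sig^2)), tolerance = 0.1)
})

test_that("a blur-free edge is limited by the pixel-aperture sinc", {
  g <- phantom_slanted_edge(3, c(26, 26), 0, 1000)
  v <- rasterize_phantom(g, 0.4, supersampling = 8, n_slices = 1,
                         grid_mm = c(26, 26))
  ## the aperture MTF50 lies beyond the detector Nyquist: the slanted edge
  ## resolves it, so raise the reporting cutoff
  mt <- measure_mtf(v, roi_rect(c(0, 0), 20, 20), f_max = 2.2)
  ref <- uniroot(function(f) abs(sin(pi * f * 0.4) / (pi * f * 0.4)) - 0.5,
                 c(0.5, 2))$root
  expect_equal(attr(mt, "mtf50"), ref, tolerance = 0.1)
})

test_that("stronger blur always lowers MTF50 and MTF10", {
  g <- phantom_slanted_edge(3, c(22, 22), 0, 1000)
  res <- lapply(c(0.5, 1.0), function(fw) {
    model <- acquisition_model(blur_fwhm = fw, noise_sd_ref = 0,
                               cupping_amplitude = 0, voxel_size = 0.2)
    vol <- simulate_acquisition(g, model, protocol_meta("T", 1, 0.2),
                                n_slices = 1,
                                window = list(center = c(0, 0), size = c(22, 22)))
    glance(measure_mtf(vol, roi_rect(c(0, 0), 16, 16), f_max = 3))
  })
  expect_gt(res[[1]]$mtf50, res[[2]]$mtf50)
  expect_gt(res[[1]]$mtf10, res[[2]]$mtf10)
  expect_gte(res[[1]]$mtf10, res[[1]]$mtf50)
})

test_that("MTF is invariant under HU offset, scaling and polarity reversal", {
  g <- phantom_slanted_edge(3, c(22, 22), 0, 1000)
  model <- acquisition_model(blur_fwhm = 0.8, noise_sd_ref = 0,
                             cupping_amplitude = 0, voxel_size = 0.4)
  vol <- simulate_acquisition(g, model, protocol_meta("T", 1, 0.4), n_slices = 1,
                              window = list(center = c(0, 0), size = c(22, 22)))
  roi <- roi_rect(c(0, 0), 16, 16)
  base <- measure_mtf(vol, roi)
  tr <- vol; tr$voxels <- 2.5 * vol$voxels - 300
  expect_equal(measure_mtf(tr, roi)$modulation, base$modulation,
               tolerance = 1e-8)
  flip <- vol; flip$voxels <- -vol$voxels
  expect_equal(measure_mtf(flip, roi)$modulation, base$modulation,
               tolerance = 1e-8)
})
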