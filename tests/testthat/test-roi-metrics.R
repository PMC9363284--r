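# ROI statistics and the metrics built on them: uniformity, HU accuracy,
# CNR, CNRD, LCV.

test_that("ROI statistics equal a brute-force voxel loop to machine precision", {
  vol <- random_scene(11)
  rois <- list(roi_circle(c(3, -5), 12), roi_rect(c(-4, 6), 10, 14))
  for (roi in rois) {
    got <- extract_roi_stats(vol, roi, slices = 1:3)
    ora <- oracle_roi_stats(vol, roi, 1:3)
    expect_identical(got$n, ora$n)
    expect_equal(got$mean, ora$mean, tolerance = 1e-12)
    expect_equal(got$sd, ora$sd, tolerance = 1e-12)
  }
})

test_that("constant and half/half regions give the textbook statistics", {
  v <- volume_image(array(120, c(20, 20, 1)), 1)
  st <- extract_roi_stats(v, roi_circle(c(0, 0), 12), 1)
  expect_equal(st$mean, 120)
  expect_equal(st$sd, 0)
  ## rectangle half in 0 HU, half in 100 HU
  m <- matrix(0, 20, 20); m[, 11:20] <- 100
  v2 <- volume_image(array(m, c(20, 20, 1)), 1)
  st2 <- extract_roi_stats(v2, roi_rect(c(0, 0), 10, 10), 1)
  expect_equal(st2$mean, 50)
})

test_that("out-of-bounds and too-small ROIs are rejected", {
  vol <- random_scene(12)
  expect_error(extract_roi_stats(vol, roi_circle(c(30, 0), 20)),
               class = "phantomqc_roi_oob")
  expect_error(extract_roi_stats(vol, roi_circle(c(0, 0), 2), 1),
               class = "phantomqc_roi_too_small")
})

test_that("uniformity follows its defining sum and flags bad layouts", {
  ## uniform volume: exactly zero, both variants
  v <- volume_image(array(100, c(120, 120, 3)), 1)
  lay <- list(central = roi_circle(c(0, 0), 10),
              peripheral = list(roi_circle(c(0, 40), 10), roi_circle(c(40, 0), 10),
                                roi_circle(c(0, -40), 10), roi_circle(c(-40, 0), 10)))
  u <- compute_uniformity(v, lay)
  expect_identical(u$uniformity, 0)
  expect_identical(u$uniformity_abs, 0)
  ## center 100, periphery 90: +10 exactly
  m <- matrix(90, 120, 120)
  xs <- (seq_len(120) - 60.5); ys <- xs
  ctr <- outer(ys^2, xs^2, "+") <= 15^2
  m[ctr] <- 100
  v2 <- volume_image(array(rep(m, 3), c(120, 120, 3)), 1)
  u2 <- compute_uniformity(v2, lay)
  expect_equal(u2$uniformity, 10)
  expect_equal(u2$uniformity_abs, 10)
  expect_gte(u2$uniformity_abs, abs(u2$uniformity))
  ## wrong ROI count
  bad <- lay; bad$peripheral <- bad$peripheral[1:3]
  expect_error(compute_uniformity(v, bad), class = "phantomqc_bad_roi")
})

test_that("default uniformity layout sits 10 mm inside the rim", {
  g <- phantom_uniformity()
  lay <- default_uniformity_layout(g)
  rads <- vapply(lay$peripheral, function(r) sqrt(sum(r$center^2)), numeric(1))
  expect_equal(rads, rep(60, 4))
  expect_equal(lay$central$center, c(0, 0))
  expect_equal(lay$central$diameter, 10)
  ## auto-detected center agrees with the simulated center within a voxel
  vol <- rasterize_phantom(g, 0.8, n_slices = 1)
  lay2 <- default_uniformity_layout(vol)
  expect_lt(max(abs(lay2$central$center)), 0.8)
  expect_equal(sqrt(sum(lay2$peripheral[[1]]$center^2)), 60, tolerance = 1)
})

test_that("cupped uniformity matches the pixel-sum oracle within 0.5 HU", {
  g <- phantom_uniformity()
  vol <- rasterize_phantom(g, 0.8, n_slices = 3)
  cup <- apply_cupping(vol, g, -50)
  lay <- default_uniformity_layout(g)
  got <- compute_uniformity(cup, lay)
  per <- vapply(lay$peripheral, oracle_cupping_roi_mean, numeric(1),
                vol = cup, amplitude = -50, R = 70)
  expected <- oracle_cupping_roi_mean(cup, lay$central, -50, 70) - mean(per)
  expect_lt(abs(got$uniformity - expected), 0.5)
  ## amplitude 0: exactly zero
  u0 <- compute_uniformity(vol, lay)
  expect_identical(u0$uniformity, 0)
})

test_that("CNR and LCV follow their defining ratios and guard degenerate SDs", {
  ## piecewise-constant scene with known means, plus a noisy background strip
  set.seed(21)
  m <- matrix(0, 80, 80)
  xs <- seq_len(80) - 40.5; ys <- xs
  tb <- outer(ys^2, (xs - 20)^2, "+") <= 8^2
  m[tb] <- 200
  v <- volume_image(array(rep(m, 1), c(80, 80, 1)), 1)
  noise <- matrix(rnorm(80 * 80, 0, 10), 80, 80)
  v$voxels[, , 1] <- v$voxels[, , 1] + noise
  roi_tb <- roi_circle(c(20, 0), 12)
  roi_w <- roi_circle(c(-20, 0), 12)
  roi_bg <- roi_circle(c(0, 25), 12)
  got <- compute_cnr(v, roi_tb, roi_w, roi_bg, 1)
  tbs <- extract_roi_stats(v, roi_tb, 1); ws <- extract_roi_stats(v, roi_w, 1)
  bgs <- extract_roi_stats(v, roi_bg, 1)
  expect_equal(got, abs(tbs$mean - ws$mean) / bgs$sd, tolerance = 1e-12)
  expect_equal(compute_cnr(v, roi_tb, roi_tb, roi_bg, 1), 0)
  ## noise-free input: undefined CNR, not infinity
  v0 <- volume_image(array(5, c(60, 60, 1)), 1)
  r <- roi_circle(c(0, 0), 12)
  expect_error(compute_cnr(v0, r, r, r, 1), class = "phantomqc_undefined_cnr")
  expect_error(compute_lcv(v0, r, r, 1), class = "phantomqc_undefined_lcv")
  ## LCV from known means/SDs: m_w 0, m_br 30, sd ~10 each
  v$voxels[, , 1] <- noise
  br <- roi_circle(c(20, 0), 12)
  v$voxels[, , 1][tb] <- v$voxels[, , 1][tb] + 30
  lcv <- compute_lcv(v, roi_w, br, 1)
  ws2 <- extract_roi_stats(v, roi_w, 1); brs <- extract_roi_stats(v, br, 1)
  expect_equal(lcv, 2 * abs(ws2$mean - brs$mean) / (ws2$sd + brs$sd),
               tolerance = 1e-12)
})

test_that("CNR and LCV are invariant under a global HU offset; uniformity scales", {
  g <- phantom_contrast_box()
  model <- acquisition_model(blur_fwhm = 0.7, noise_sd_ref = 20, ctdi_ref = 1,
                             cupping_amplitude = 0, voxel_size = 0.8, seed = 31L)
  vol <- simulate_acquisition(g, model, protocol_meta("T", 1, 0.8), n_slices = 3)
  lay <- default_contrast_layout(g)
  shifted <- vol; shifted$voxels <- vol$voxels + 137
  expect_equal(compute_cnr(shifted, lay$bone, lay$water, lay$background),
               compute_cnr(vol, lay$bone, lay$water, lay$background),
               tolerance = 1e-10)
  expect_equal(compute_lcv(shifted, lay$water, lay$breast),
               compute_lcv(vol, lay$water, lay$breast), tolerance = 1e-10)

  gu <- phantom_uniformity()
  vu <- apply_cupping(rasterize_phantom(gu, 0.8, n_slices = 1), gu, -40)
  layu <- default_uniformity_layout(gu)
  u <- compute_uniformity(vu, layu)$uniformity
  vu2 <- vu; vu2$voxels <- vu$voxels * 2 + 100
  expect_equal(compute_uniformity(vu2, layu)$uniformity, 2 * u, tolerance = 1e-9)
})

test_that("CNRD and HU error arithmetic reproduce hand calculations", {
  expect_equal(round_half_away(compute_cnrd(7.2, 0.5)), 10.2)
  expect_equal(round_half_away(compute_cnrd(11.4, 1.4)), 9.6)
  expect_identical(compute_cnrd(0, 2.5), 0)
  expect_error(compute_cnrd(5, 0), class = "phantomqc_bad_dose")
  expect_equal(round_half_away(hu_error_percent(1429.5, 990)), 44.4)
  expect_equal(round_half_away(hu_error_percent(9.6, -120)), 108.0)
  expect_identical(hu_error_percent(990, 990), 0)
  expect_error(hu_error_percent(3, 0), class = "phantomqc_zero_nominal")
})

test_that("HU-accuracy analysis recovers nominals on clean phantoms", {
  g <- phantom_hu_inserts()
  vol <- rasterize_phantom(g, 0.4, n_slices = 3)
  res <- analyze_hu_phantom(vol, geometry = g)
  expect_setequal(res$material, c("air", "pmma", "pvc", "ptfe"))
  expect_equal(res$error_percent, rep(0, 4))
  ## blurred but noise-free, 2 mm ROI margin: errors stay below 0.5%
  blr <- apply_system_blur(vol, 0.7)
  res2 <- analyze_hu_phantom(blr, geometry = g)
  expect_true(all(res2$error_percent < 0.5))
  ## noisy phantom: measured means within 3 SEM of nominals
  model <- acquisition_model(blur_fwhm = 0.7, noise_sd_ref = 15, ctdi_ref = 1,
                             cupping_amplitude = 0, voxel_size = 0.4, seed = 8L)
  noisy <- simulate_acquisition(g, model, protocol_meta("T", 1, 0.4), n_slices = 3)
  res3 <- analyze_hu_phantom(noisy, geometry = g)
  lay <- default_hu_layout(g)
  for (i in seq_len(nrow(res3))) {
    st <- extract_roi_stats(noisy, lay[[res3$material[i]]])
    expect_lt(abs(res3$offset_hu[i]), 3 * 15 / sqrt(st$n) + 0.5)
  }
  ## an ROI hugging the insert boundary trips the margin guard
  bad <- lay; bad$ptfe <- roi_circle(c(-14, 0), 14.5)
  expect_error(analyze_hu_phantom(vol, bad, geometry = g),
               class = "phantomqc_roi_margin")
})

test_that("contrast-phantom CNR approaches its analytic expectation", {
  g <- phantom_contrast_box()
  model <- acquisition_model(blur_fwhm = 0.7, noise_sd_ref = 20, ctdi_ref = 1,
                             cupping_amplitude = 0, voxel_size = 0.4, seed = 17L)
  vols <- lapply(1:5, function(s)
    simulate_acquisition(g, model, protocol_meta("T", 1, 0.4), n_slices = 3,
                         seed = 400 + s))
  cnrs <- vapply(vols, function(v)
    analyze_contrast_phantom(v, geometry = g, ctdi_vol = 1)$cnr, numeric(1))
  lcvs <- vapply(vols, function(v)
    analyze_contrast_phantom(v, geometry = g, ctdi_vol = 1)$lcv, numeric(1))
  ## bone +280, water 0, sigma 20: CNR ~ 14; breast -45: LCV ~ 2.25
  expect_equal(mean(cnrs), 14, tolerance = 0.1)
  expect_equal(mean(lcvs), 2.25, tolerance = 0.12)
})
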