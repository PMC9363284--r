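## Image-domain degradation model: Gaussian system blur, radial cupping
## bias, and dose-scaled white Gaussian noise. These are surrogates for the
## image-quality differences the metrics are meant to detect — known blur
## gives a known ground-truth MTF, the noise law makes CNRD dose-invariant
## by construction, and cupping emulates the scatter-driven center-to-edge
## bias typical of cone-beam systems.

#' Acquisition degradation model
#'
#' Bundles the degradation parameters of a simulated acquisition. Noise
#' applied at dose D has SD `noise_sd_ref * sqrt(ctdi_ref / D)`, the
#' standard quantum-noise dose law, so the dose-normalized CNR (CNRD) is
#' dose-invariant by construction.
#'
#' @param blur_fwhm In-plane Gaussian PSF full width at half maximum, mm.
#' @param noise_sd_ref Noise SD in HU at the reference dose.
#' @param ctdi_ref Reference dose (CTDIvol, mGy) at which `noise_sd_ref`
#'   applies.
#' @param cupping_amplitude Center-minus-edge HU bias; negative depresses
#'   the center (classic cupping), positive raises it (capping).
#' @param voxel_size Default reconstruction voxel pitch in mm.
#' @param seed Integer seed from which all simulation randomness flows.
#' @return An `acquisition_model` object.
#' @export
acquisition_model <- function(blur_fwhm = 0.7, noise_sd_ref = 28,
                              ctdi_ref = 1.0, cupping_amplitude = -60,
                              voxel_size = 0.4, seed = 1L) {
  check_that(blur_fwhm >= 0, "`blur_fwhm` must be >= 0.", "phantomqc_bad_arg")
  check_that(noise_sd_ref >= 0, "`noise_sd_ref` must be >= 0.", "phantomqc_bad_arg")
  check_that(ctdi_ref > 0, "`ctdi_ref` must be > 0.", "phantomqc_bad_arg")
  check_that(voxel_size > 0, "`voxel_size` must be > 0.", "phantomqc_bad_arg")
  structure(list(blur_fwhm = blur_fwhm, noise_sd_ref = noise_sd_ref,
                 ctdi_ref = ctdi_ref, cupping_amplitude = cupping_amplitude,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "acquisition_model")
}

#' Acquisition protocol metadata
#'
#' @param label Protocol label, e.g. "ULD", "LD", "DF".
#' @param ctdi_vol Volume CT dose index in mGy (required for CNRD).
#' @param voxel_size In-plane voxel size in mm.
#' @param device Device label.
#' @return A `protocol_meta` object.
#' @export
protocol_meta <- function(label, ctdi_vol, voxel_size, device = "sim") {
  check_that(is.na(ctdi_vol) || ctdi_vol > 0, "`ctdi_vol` must be > 0.",
             "phantomqc_bad_dose")
  check_that(voxel_size > 0, "`voxel_size` must be > 0.", "phantomqc_bad_arg")
  structure(list(label = label, ctdi_vol = ctdi_vol,
                 voxel_size = voxel_size, device = device),
            class = "protocol_meta")
}

#' Study protocol presets
#'
#' The nine acquisition protocols of the three-scanner sinus-imaging study:
#' ultra-low-dose (ULD), low-dose (LD) and default (DF) settings for a
#' dental CBCT, an extremity CBCT and a clinical MDCT, with their CTDIvol
#' and in-plane voxel size.
#'
#' @return A tibble with columns `device`, `protocol`, `ctdi_mgy`,
#'   `voxel_mm`.
#' @export
protocol_presets <- function() {
  tibble(
    device = rep(c("dental_cbct", "extremity_cbct", "mdct"), each = 3),
    protocol = rep(c("ULD", "LD", "DF"), 3),
    ctdi_mgy = c(0.5, 1.3, 3.7, 0.6, 1.4, 3.9, 0.6, 1.4, 7.0),
    voxel_mm = c(0.4, 0.4, 0.2, 0.4, 0.4, 0.2, 0.4, 0.4, 0.4))
}

## 1-D blur matrix: erf-integrated Gaussian taps at unit pixel pitch,
## truncated at 4 sigma, rows renormalized (conserves constants at borders)
blur_matrix <- function(n, sigma_px) {
  if (sigma_px < 1e-8) return(diag(n))
  m <- max(1L, ceiling(4 * sigma_px))
  k <- -m:m
  w <- stats::pnorm((k + 0.5) / sigma_px) - stats::pnorm((k - 0.5) / sigma_px)
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    d <- k[j]
    i <- seq_len(n)
    tgt <- i + d
    ok <- tgt >= 1 & tgt <= n
    K[cbind(tgt[ok], i[ok])] <- K[cbind(tgt[ok], i[ok])] + w[j]
  }
  sweep(K, 1, rowSums(K), "/")
}

#' Apply isotropic in-plane Gaussian system blur
#'
#' Convolves each axial slice with a Gaussian of the stated FWHM using
#' pixel-integrated kernel taps. Accurate when the FWHM is not much smaller
#' than the voxel pitch; [simulate_acquisition()] instead blurs on a finer
#' render grid so its realized MTF follows the closed form even at
#' sub-voxel FWHM.
#'
#' @param vol A [volume_image()].
#' @param blur_fwhm Gaussian FWHM in mm; 0 returns the input unchanged.
#' @return The blurred [volume_image()].
#' @export
apply_system_blur <- function(vol, blur_fwhm) {
  check_that(is_volume_image(vol), "`vol` must be a volume_image.", "phantomqc_bad_volume")
  check_that(blur_fwhm >= 0, "`blur_fwhm` must be >= 0.", "phantomqc_bad_arg")
  if (blur_fwhm == 0) return(vol)
  sig <- fwhm_to_sigma(blur_fwhm)
  d <- dim(vol$voxels)
  Ky <- blur_matrix(d[1], sig / vol$spacing[2])
  Kx <- blur_matrix(d[2], sig / vol$spacing[1])
  out <- vol
  for (k in seq_len(d[3]))
    out$voxels[, , k] <- Ky %*% vol$voxels[, , k] %*% t(Kx)
  out
}

#' Apply a radial cupping/capping bias
#'
#' Adds a radially parabolic HU bias `b(r) = amplitude * (1 - (r/R)^2)`
#' inside the phantom (R is the geometry's outer radius; for a box, its
#' circumscribed radius) and nothing outside — the minimal smooth
#' center-to-edge model of the scatter-driven cupping artifact seen in
#' cone-beam CT.
#'
#' @param vol A [volume_image()].
#' @param geometry The `phantom_geometry` the volume depicts (provides the
#'   axis and outer radius).
#' @param amplitude Center bias in HU; negative = cupping, positive =
#'   capping, 0 = identity.
#' @return The biased [volume_image()].
#' @export
apply_cupping <- function(vol, geometry, amplitude) {
  check_that(is_volume_image(vol), "`vol` must be a volume_image.", "phantomqc_bad_volume")
  check_that(inherits(geometry, "phantom_geometry") && is.finite(geometry$cupping_radius),
             "`geometry` does not define a phantom axis and outer radius.",
             "phantomqc_bad_geometry")
  if (amplitude == 0) return(vol)
  R <- geometry$cupping_radius
  body <- geometry$regions[[1]]
  xs <- vol_x(vol); ys <- vol_y(vol)
  r2 <- outer(ys^2, xs^2, "+")
  inside <- matrix(region_indicator(body, rep(xs, each = length(ys)),
                                    rep(ys, times = length(xs))),
                   length(ys), length(xs))
  bias <- amplitude * (1 - r2 / R^2) * inside
  out <- vol
  for (k in seq_len(dim(vol$voxels)[3])) {
    z <- vol_z(vol)[k]
    if (z >= body$zmin && z <= body$zmax)
      out$voxels[, , k] <- vol$voxels[, , k] + bias
  }
  out
}

#' Add dose-scaled white Gaussian noise
#'
#' Adds zero-mean Gaussian noise with SD `noise_sd_ref * sqrt(ctdi_ref /
#' ctdi)` — noise falls with the square root of dose, which is exactly the
#' relationship that makes CNR / sqrt(CTDIvol) a dose-neutral figure of
#' merit.
#'
#' @param vol A [volume_image()].
#' @param model An [acquisition_model()].
#' @param ctdi Dose (CTDIvol, mGy) of this acquisition; must be > 0.
#' @param seed Integer seed (defaults to the model's seed).
#' @return The noisy [volume_image()].
#' @export
add_dose_scaled_noise <- function(vol, model, ctdi, seed = model$seed) {
  check_that(is_volume_image(vol), "`vol` must be a volume_image.", "phantomqc_bad_volume")
  check_that(ctdi > 0, "`ctdi` must be > 0.", "phantomqc_bad_dose")
  sd_hu <- model$noise_sd_ref * sqrt(model$ctdi_ref / ctdi)
  if (sd_hu == 0) return(vol)
  out <- vol
  withr::with_seed(as.integer(seed), {
    out$voxels <- vol$voxels + array(rnorm(length(vol$voxels), 0, sd_hu),
                                     dim(vol$voxels))
  })
  out
}

#' Simulate a full phantom acquisition
#'
#' Composition rasterize -> blur -> cupping -> noise. The blur is applied on
#' a `render_scale`-finer grid which is then block-averaged to the detector
#' voxels, so the realized in-plane system MTF is the closed-form product of
#' the Gaussian PSF transfer function and the square pixel aperture — the
#' ground truth used by the edge-method recovery tests. Deterministic given
#' `(geometry, model, protocol, seed)`.
#'
#' @param geometry A `phantom_geometry`.
#' @param model An [acquisition_model()].
#' @param protocol A [protocol_meta()]; its `voxel_size` (if it differs from
#'   the model's by more than 1e-9) must be intended — a mismatch is an
#'   error.
#' @param n_slices Number of axial slices (default 5).
#' @param supersampling Effective sub-voxel sampling for partial volume.
#' @param render_scale Fine-grid factor for blur rendering (default 4).
#' @param seed Integer seed (defaults to the model's seed).
#' @param window Optional in-plane sub-window, as in [rasterize_phantom()].
#' @return A [volume_image()] whose `$provenance` records the ground-truth
#'   parameters for recovery tests.
#' @export
simulate_acquisition <- function(geometry, model, protocol,
                                 n_slices = 5L, supersampling = 8L,
                                 render_scale = 4L, seed = model$seed,
                                 window = NULL) {
  check_that(inherits(model, "acquisition_model"), "`model` must be an acquisition_model.",
             "phantomqc_bad_arg")
  check_that(inherits(protocol, "protocol_meta"), "`protocol` must be a protocol_meta.",
             "phantomqc_bad_arg")
  if (!is.null(model$voxel_size) &&
      abs(model$voxel_size - protocol$voxel_size) > 1e-9 &&
      !isTRUE(attr(model, "voxel_free")))
    warn("Model and protocol voxel sizes differ; using the protocol's.")
  v <- protocol$voxel_size
  rs <- as.integer(render_scale)
  if (model$blur_fwhm == 0) rs <- 1L
  ss_fine <- max(1L, as.integer(ceiling(supersampling / rs)))
  ## detector grid (odd counts: a voxel center sits on the axis), then an
  ## exact rs-fold refinement of it for blur rendering
  if (!is.null(window)) {
    nx <- odd_count(window$size[1], v); ny <- odd_count(window$size[2], v)
    cx <- window$center[1]; cy <- window$center[2]
  } else {
    ext <- geometry$extent_mm + 2 * 6
    nx <- odd_count(ext[1], v); ny <- odd_count(ext[2], v)
    cx <- 0; cy <- 0
  }
  xs <- cx + (seq_len(nx) - (nx + 1) / 2) * v
  ys <- cy + (seq_len(ny) - (ny + 1) / 2) * v
  zc <- geometry$height_mm / 2
  zs <- zc + (seq_len(n_slices) - (n_slices + 1) / 2) * v
  vf <- v / rs
  xf <- rep(xs, each = rs) + (seq_len(rs) - (rs + 1) / 2) * vf
  yf <- rep(ys, each = rs) + (seq_len(rs) - (rs + 1) / 2) * vf
  finev <- rasterize_grid(geometry, xf, yf, zs, vf, ss_fine)
  fine <- volume_image(finev, c(vf, vf, v), origin = c(xf[1], yf[1], zs[1]))
  fine <- apply_system_blur(fine, model$blur_fwhm)
  vox <- array(0, c(ny, nx, n_slices))
  for (k in seq_len(n_slices)) vox[, , k] <- block_mean(fine$voxels[, , k], rs)
  vol <- volume_image(vox, c(v, v, v), origin = c(xs[1], ys[1], zs[1]),
                      modality = paste0("SIM/", protocol$device))
  vol <- apply_cupping2(vol, geometry, model$cupping_amplitude)
  vol <- add_dose_scaled_noise(vol, model, protocol$ctdi_vol, seed = seed)
  vol$provenance <- list(kind = geometry$kind, model = unclass(model),
                         protocol = unclass(protocol), seed = as.integer(seed),
                         n_slices = n_slices, render_scale = rs)
  vol
}

## cupping that tolerates geometries without an axis (slanted edge): no-op
apply_cupping2 <- function(vol, geometry, amplitude) {
  if (amplitude == 0 || !is.finite(geometry$cupping_radius)) return(vol)
  apply_cupping(vol, geometry, amplitude)
}
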