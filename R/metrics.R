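## ROI-statistic image-quality metrics: uniformity, HU accuracy, CNR,
## CNRD and low-contrast visibility.

#' Default five-ROI uniformity layout
#'
#' One central 10 mm ROI on the phantom axis and four 10 mm ROIs at the
#' 3, 6, 9 and 12 o'clock positions, their centers set in from the phantom
#' rim by `rim_inset_mm`. The phantom center and radius come from the
#' geometry, or are auto-detected from a volume by thresholding against air
#' and taking the centroid and equivalent-area radius of the mask.
#'
#' @param x A `phantom_geometry` or a [volume_image()].
#' @param roi_diameter_mm ROI diameter in mm (default 10).
#' @param rim_inset_mm Distance of peripheral ROI centers from the rim
#'   (default 10 mm).
#' @param threshold_hu Air threshold for auto-detection (default -500).
#' @return `list(central = roi, peripheral = list of 4 rois)`.
#' @export
default_uniformity_layout <- function(x, roi_diameter_mm = 10,
                                      rim_inset_mm = 10, threshold_hu = -500) {
  if (inherits(x, "phantom_geometry")) {
    ctr <- c(0, 0); R <- x$cupping_radius
  } else if (is_volume_image(x)) {
    k <- ceiling(dim(x$voxels)[3] / 2)
    m <- x$voxels[, , k] > threshold_hu
    check_that(any(m), "No phantom detected above the air threshold.",
               "phantomqc_no_phantom")
    xs <- vol_x(x); ys <- vol_y(x)
    w <- which(m, arr.ind = TRUE)
    ctr <- c(mean(xs[w[, 2]]), mean(ys[w[, 1]]))
    R <- sqrt(sum(m) * x$spacing[1] * x$spacing[2] / pi)
  } else {
    abort("`x` must be a phantom_geometry or volume_image.", class = "phantomqc_bad_arg")
  }
  rp <- R - rim_inset_mm
  check_that(rp > roi_diameter_mm / 2, "Phantom too small for the requested layout.",
             "phantomqc_bad_roi")
  at <- function(dx, dy, lab) roi_circle(ctr + c(dx, dy), roi_diameter_mm, lab)
  list(central = at(0, 0, "central"),
       peripheral = list(at(0, rp, "p12"), at(rp, 0, "p3"),
                         at(0, -rp, "p6"), at(-rp, 0, "p9")))
}

#' Image uniformity from a five-ROI layout
#'
#' The signed uniformity is the mean difference between the central ROI mean
#' and the four peripheral ROI means,
#' \eqn{U = \frac{1}{4}\sum_i (m_c - m_{p,i})}. Because a cupped image gives
#' a negative signed value while QA reports conventionally quote magnitudes,
#' the absolute variant (mean of the absolute differences) is reported
#' alongside; the signed value is primary.
#'
#' @param vol A [volume_image()].
#' @param layout `list(central = roi, peripheral = list of 4 rois)`, e.g.
#'   from [default_uniformity_layout()].
#' @param slices Slice selection, as in [extract_roi_stats()].
#' @return A `uniformity_result`: `uniformity`, `uniformity_abs`, and the
#'   contributing ROI statistics.
#' @export
compute_uniformity <- function(vol, layout, slices = NULL) {
  check_that(!is.null(layout$central) && length(layout$peripheral) == 4L,
             "Layout must hold exactly one central and four peripheral ROIs.",
             "phantomqc_bad_roi")
  ctr <- extract_roi_stats(vol, layout$central, slices)
  per <- purrr::map_dfr(layout$peripheral, extract_roi_stats, vol = vol,
                        slices = slices)
  diffs <- ctr$mean - per$mean
  structure(
    list(uniformity = mean(diffs), uniformity_abs = mean(abs(diffs)),
         central = ctr, peripheral = per),
    class = "uniformity_result")
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("<uniformity_result> uniformity %.1f HU (|.| variant %.1f HU)\n",
              x$uniformity, x$uniformity_abs))
  invisible(x)
}

#' @export
tidy.uniformity_result <- function(x, ...) {
  dplyr::bind_rows(x$central, x$peripheral)
}

#' @export
glance.uniformity_result <- function(x, ...) {
  tibble(uniformity = x$uniformity, uniformity_abs = x$uniformity_abs)
}

#' Contrast-to-noise ratio
#'
#' `CNR = |m_tb - m_w| / sigma_bg`: the absolute difference between the
#' trabecular-bone and water ROI means over the background ROI's SD.
#'
#' @param vol A [volume_image()].
#' @param roi_tb,roi_w,roi_bg Bone, water and background ROIs.
#' @param slices Slice selection.
#' @return CNR (non-negative scalar).
#' @export
compute_cnr <- function(vol, roi_tb, roi_w, roi_bg, slices = NULL) {
  tb <- extract_roi_stats(vol, roi_tb, slices)
  w <- extract_roi_stats(vol, roi_w, slices)
  bg <- extract_roi_stats(vol, roi_bg, slices)
  check_that(bg$sd > 0,
             "Background SD is zero (noise-free input): CNR is undefined.",
             "phantomqc_undefined_cnr")
  abs(tb$mean - w$mean) / bg$sd
}

#' Dose-normalized contrast-to-noise ratio
#'
#' `CNRD = CNR / sqrt(CTDIvol)` — under the quantum-noise dose law
#' (noise SD proportional to 1/sqrt(dose)) this figure is dose-invariant,
#' which is what makes protocols with different doses comparable.
#'
#' @param cnr Contrast-to-noise ratio.
#' @param ctdi_vol Dose (CTDIvol) in mGy; must be > 0.
#' @return CNRD (scalar, per sqrt(mGy)).
#' @export
compute_cnrd <- function(cnr, ctdi_vol) {
  check_that(all(ctdi_vol > 0), "`ctdi_vol` must be > 0 for CNRD.",
             "phantomqc_bad_dose")
  cnr / sqrt(ctdi_vol)
}

#' Low-contrast visibility
#'
#' `LCV = 2 |m_w - m_br| / (sigma_w + sigma_br)`: the water/breast-rod mean
#' difference over the average of their SDs.
#'
#' @param vol A [volume_image()].
#' @param roi_w,roi_br Water and breast-rod ROIs.
#' @param slices Slice selection.
#' @return LCV (non-negative scalar).
#' @export
compute_lcv <- function(vol, roi_w, roi_br, slices = NULL) {
  w <- extract_roi_stats(vol, roi_w, slices)
  br <- extract_roi_stats(vol, roi_br, slices)
  check_that(w$sd + br$sd > 0,
             "Both ROI SDs are zero: LCV is undefined.",
             "phantomqc_undefined_lcv")
  2 * abs(w$mean - br$mean) / (w$sd + br$sd)
}

#' Hounsfield-unit error percentage
#'
#' `100 * |measured - nominal| / |nominal|`. Undefined for water
#' (nominal 0); report the absolute HU offset for water instead.
#'
#' @param measured Measured mean HU (vectorized).
#' @param nominal Nominal HU (vectorized, nonzero).
#' @return Error percentage(s), full precision (round at reporting).
#' @export
hu_error_percent <- function(measured, nominal) {
  check_that(all(nominal != 0),
             "`nominal` must be nonzero; water accuracy is an absolute HU offset.",
             "phantomqc_zero_nominal")
  100 * abs(measured - nominal) / abs(nominal)
}

#' Default per-insert ROI layout for the HU-accuracy phantom
#'
#' One circular ROI per insert, centered on the insert, with the stated
#' margin kept between the ROI edge and the insert boundary so blur at the
#' boundary does not leak into the measurement.
#'
#' @param geometry A `phantom_geometry` of kind `hu_insert_cylinder`.
#' @param margin_mm Margin between ROI edge and insert edge (default 2 mm).
#' @return Named list of [roi_circle()]s, one per insert material.
#' @export
default_hu_layout <- function(geometry, margin_mm = 2) {
  check_that(geometry$kind == "hu_insert_cylinder",
             "Layout is defined for the HU-insert cylinder.", "phantomqc_bad_geometry")
  ins <- geometry$regions[-1]
  rois <- lapply(ins, function(r) {
    d <- 2 * (r$radius - margin_mm)
    check_that(d > 0, "Margin leaves no ROI area inside the insert.", "phantomqc_bad_roi")
    roi_circle(r$center, d, r$material)
  })
  stats::setNames(rois, vapply(ins, function(r) r$material, character(1)))
}

#' HU accuracy of the insert phantom
#'
#' Measures each insert's mean HU and compares it with the nominal value.
#' Each ROI must sit inside its insert with a safety margin (default 1 mm)
#' so partial-volume and blur at the boundary are excluded.
#'
#' @param vol A [volume_image()].
#' @param layout Named list of ROIs, one per insert material; default from
#'   [default_hu_layout()] when `geometry` is supplied.
#' @param geometry Optional `phantom_geometry` used to build the default
#'   layout and to enforce the margin guard.
#' @param materials Material library (for nominal HUs).
#' @param slices Slice selection.
#' @param guard_margin_mm Minimum ROI-edge-to-insert-edge distance.
#' @return A `hu_accuracy_result` tibble: `material`, `nominal_hu`,
#'   `measured_hu`, `error_percent` (NA where nominal is 0), `offset_hu`.
#' @export
analyze_hu_phantom <- function(vol, layout = NULL, geometry = NULL,
                               materials = material_library(), slices = NULL,
                               guard_margin_mm = 1) {
  if (is.null(layout)) {
    check_that(!is.null(geometry), "Provide a layout or a geometry.", "phantomqc_bad_arg")
    layout <- default_hu_layout(geometry)
  }
  if (!is.null(geometry)) {
    ins <- geometry$regions[-1]
    for (nm in names(layout)) {
      reg <- ins[[which(vapply(ins, function(r) r$material, character(1)) == nm)[1]]]
      roi <- layout[[nm]]
      slack <- reg$radius - sqrt(sum((roi$center - reg$center)^2)) - roi$diameter / 2
      check_that(slack >= guard_margin_mm,
                 sprintf("ROI '%s' is within %.2f mm of its insert boundary.", nm, slack),
                 "phantomqc_roi_margin")
    }
  }
  res <- purrr::imap_dfr(layout, function(roi, nm) {
    st <- extract_roi_stats(vol, roi, slices)
    nom <- material_hu(nm, materials)
    tibble(material = nm, nominal_hu = nom, measured_hu = st$mean,
           error_percent = if (nom == 0) NA_real_ else hu_error_percent(st$mean, nom),
           offset_hu = st$mean - nom)
  })
  class(res) <- c("hu_accuracy_result", class(res))
  res
}

#' Default ROI layout for the contrast phantom
#'
#' Water and background ROIs (10 mm) in the edge-midspan water channels —
#' the only water pockets of the tightly packed box that keep 5 mm clearance
#' from every rod — plus 20 mm ROIs inside a breast rod and the central bone
#' rod.
#'
#' @param geometry A `phantom_geometry` of kind `contrast_box`.
#' @param roi_diameter_mm Water/background ROI diameter (default 10).
#' @param rod_roi_diameter_mm Rod ROI diameter (default 20, i.e. 5 mm inside
#'   a 30 mm rod).
#' @return Named list of ROIs: `water`, `background`, `breast`, `bone`.
#' @export
default_contrast_layout <- function(geometry, roi_diameter_mm = 10,
                                    rod_roi_diameter_mm = 20) {
  check_that(geometry$kind == "contrast_box",
             "Layout is defined for the contrast box.", "phantomqc_bad_geometry")
  rods <- geometry$regions[-1]
  mats <- vapply(rods, function(r) r$material, character(1))
  breast <- rods[[which(mats == "breast")[1]]]
  bone <- rods[[which(mats == "bone")[1]]]
  hh <- geometry$regions[[1]]$half_h
  ychan <- hh - roi_diameter_mm / 2 - 1.5   # edge-midspan water channel
  list(water = roi_circle(c(0, -ychan), roi_diameter_mm, "water"),
       background = roi_circle(c(0, ychan), roi_diameter_mm, "background"),
       breast = roi_circle(breast$center, rod_roi_diameter_mm, "breast"),
       bone = roi_circle(bone$center, rod_roi_diameter_mm, "bone"))
}

#' CNR, CNRD and LCV of the contrast phantom
#'
#' @param vol A [volume_image()].
#' @param layout Named ROI list (`water`, `background`, `breast`, `bone`),
#'   default from [default_contrast_layout()] when `geometry` is given.
#' @param geometry Optional `phantom_geometry` for the default layout.
#' @param ctdi_vol Dose in mGy; when given, CNRD is reported.
#' @param slices Slice selection.
#' @return A `contrast_result` with `cnr`, `cnrd`, `lcv` and the
#'   contributing ROI statistics.
#' @export
analyze_contrast_phantom <- function(vol, layout = NULL, geometry = NULL,
                                     ctdi_vol = NA_real_, slices = NULL) {
  if (is.null(layout)) {
    check_that(!is.null(geometry), "Provide a layout or a geometry.", "phantomqc_bad_arg")
    layout <- default_contrast_layout(geometry)
  }
  st <- purrr::imap_dfr(layout, function(roi, nm)
    dplyr::mutate(extract_roi_stats(vol, roi, slices), label = nm))
  cnr <- compute_cnr(vol, layout$bone, layout$water, layout$background, slices)
  lcv <- compute_lcv(vol, layout$water, layout$breast, slices)
  cnrd <- if (is.na(ctdi_vol)) NA_real_ else compute_cnrd(cnr, ctdi_vol)
  structure(list(cnr = cnr, cnrd = cnrd, lcv = lcv, ctdi_vol = ctdi_vol,
                 stats = st),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> CNR %.1f, CNRD %s, LCV %.2f\n", x$cnr,
              ifelse(is.na(x$cnrd), "n/a", sprintf("%.1f", x$cnrd)), x$lcv))
  invisible(x)
}

#' @export
tidy.contrast_result <- function(x, ...) x$stats

#' @export
glance.contrast_result <- function(x, ...) {
  tibble(cnr = x$cnr, cnrd = x$cnrd, lcv = x$lcv, ctdi_vol = x$ctdi_vol)
}
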