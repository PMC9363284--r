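## ROI placement and the measurement primitive: pooled mean/SD over the
## member voxels of a placed region.

#' Circular region of interest
#'
#' @param center In-plane center `c(x, y)` in mm (world coordinates).
#' @param diameter_mm ROI diameter in mm. A voxel belongs to the ROI iff its
#'   center lies within the radius.
#' @param label Optional label carried into results.
#' @return An `roi_spec`.
#' @export
roi_circle <- function(center, diameter_mm, label = NULL) {
  check_that(diameter_mm > 0, "`diameter_mm` must be > 0.", "phantomqc_bad_roi")
  structure(list(shape = "circle", center = as.numeric(center),
                 diameter = diameter_mm, label = label),
            class = "roi_spec")
}

#' Rectangular region of interest
#'
#' @param center In-plane center `c(x, y)` in mm.
#' @param width_mm,height_mm Extent along x and y in mm.
#' @param label Optional label.
#' @return An `roi_spec`.
#' @export
roi_rect <- function(center, width_mm, height_mm, label = NULL) {
  check_that(width_mm > 0 && height_mm > 0, "ROI extents must be > 0.",
             "phantomqc_bad_roi")
  structure(list(shape = "rect", center = as.numeric(center),
                 width = width_mm, height = height_mm, label = label),
            class = "roi_spec")
}

## logical in-plane membership mask for an roi_spec
roi_mask <- function(vol, roi) {
  xs <- vol_x(vol); ys <- vol_y(vol)
  if (roi$shape == "circle") {
    r2 <- (roi$diameter / 2)^2
    outer((ys - roi$center[2])^2, (xs - roi$center[1])^2, "+") <= r2
  } else {
    outer(abs(ys - roi$center[2]) <= roi$height / 2,
          abs(xs - roi$center[1]) <= roi$width / 2, "&")
  }
}

## ROI bounding box must lie inside the image
roi_in_bounds <- function(vol, roi) {
  xs <- vol_x(vol); ys <- vol_y(vol)
  h <- vol$spacing / 2
  ext <- if (roi$shape == "circle") rep(roi$diameter / 2, 2)
         else c(roi$width, roi$height) / 2
  roi$center[1] - ext[1] >= xs[1] - h[1] &&
    roi$center[1] + ext[1] <= xs[length(xs)] + h[1] &&
    roi$center[2] - ext[2] >= ys[1] - h[2] &&
    roi$center[2] + ext[2] <= ys[length(ys)] + h[2]
}

#' Mean and SD over a region of interest
#'
#' Pools all member voxels of the ROI across the selected slices and returns
#' their mean, sample SD (n - 1 denominator) and count. Requires at least
#' 25 voxels — the guard against degenerate SD estimates for metric-grade
#' ROIs.
#'
#' @param vol A [volume_image()].
#' @param roi An [roi_circle()] or [roi_rect()].
#' @param slices Slice indices to pool; default is the central 5-slice slab
#'   (all slices if the volume is thinner).
#' @return A one-row tibble: `mean`, `sd`, `n` (plus the ROI label if set).
#' @export
extract_roi_stats <- function(vol, roi, slices = NULL) {
  check_that(is_volume_image(vol), "`vol` must be a volume_image.", "phantomqc_bad_volume")
  check_that(inherits(roi, "roi_spec"), "`roi` must be an roi_spec.", "phantomqc_bad_roi")
  check_that(roi_in_bounds(vol, roi), "ROI extends beyond the image bounds.",
             "phantomqc_roi_oob")
  slices <- slices %||% central_slab(vol)
  check_that(length(slices) >= 1 && all(slices >= 1 & slices <= dim(vol$voxels)[3]),
             "Slice selector resolves to no valid slice.", "phantomqc_roi_oob")
  m <- roi_mask(vol, roi)
  vals <- as.vector(vapply(slices, function(k) vol$voxels[, , k][m],
                           numeric(sum(m))))
  check_that(length(vals) >= 25,
             sprintf("ROI holds only %d voxels; at least 25 are required.", length(vals)),
             "phantomqc_roi_too_small")
  tibble(label = roi$label %||% NA_character_,
         mean = mean(vals), sd = sd(vals), n = length(vals))
}
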