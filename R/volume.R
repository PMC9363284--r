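#' HU volume with voxel spacing
#'
#' A `volume_image` is the unit every metric consumes: a 3-D grid of
#' Hounsfield units plus the physical voxel spacing. Voxels are indexed
#' `[row, col, slice]`; world coordinates are millimetres of voxel centers,
#' with x running along columns, y along rows and z along slices.
#'
#' @param voxels 3-D numeric array of HU values, dim `(rows, cols, slices)`.
#'   A matrix is promoted to a single-slice volume.
#' @param spacing Voxel spacing in mm: length 3 `(x, y, z)`, length 2
#'   (in-plane, z = x), or a scalar (isotropic).
#' @param origin World coordinate (mm) of the center of voxel `[1, 1, 1]`,
#'   length 3. Defaults to centering the grid on `(0, 0)` in-plane with the
#'   first slice at z = 0.
#' @param modality Free-text modality/provenance tag.
#' @return A `volume_image` object.
#' @export
volume_image <- function(voxels, spacing, origin = NULL, modality = "SIM") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  check_that(is.array(voxels) && length(dim(voxels)) == 3L,
             "`voxels` must be a 3-D array (rows, cols, slices).",
             "phantomqc_bad_volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) == 2L) spacing <- c(spacing, spacing[1])
  check_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
             "`spacing` must be strictly positive on every axis.",
             "phantomqc_bad_spacing")
  d <- dim(voxels)
  if (is.null(origin)) {
    origin <- c(-(d[2] - 1) / 2 * spacing[1], -(d[1] - 1) / 2 * spacing[2], 0)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         modality = modality),
    class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$modality))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

is_volume_image <- function(x) inherits(x, "volume_image")

## world coordinates (mm) of voxel centers along each axis
vol_x <- function(vol) vol$origin[1] + (seq_len(dim(vol$voxels)[2]) - 1) * vol$spacing[1]
vol_y <- function(vol) vol$origin[2] + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing[2]
vol_z <- function(vol) vol$origin[3] + (seq_len(dim(vol$voxels)[3]) - 1) * vol$spacing[3]

## require square in-plane voxels (edge metrics assume isotropic sampling)
vol_pixel_mm <- function(vol) {
  if (abs(vol$spacing[1] - vol$spacing[2]) > 1e-9)
    abort("In-plane voxel spacing must be isotropic for this operation.",
          class = "phantomqc_anisotropic")
  vol$spacing[1]
}

## central slab of k slices (all slices if fewer); returns slice indices
central_slab <- function(vol, k = 5L) {
  n <- dim(vol$voxels)[3]
  k <- min(k, n)
  mid <- ceiling(n / 2)
  lo <- max(1L, mid - (k %/% 2L))
  seq(lo, length.out = k)
}

#' Probe the HU value at a world coordinate
#'
#' Returns the HU of the voxel whose center is nearest to the given world
#' position (mm). Convenience for inspecting simulated phantoms.
#'
#' @param vol A [volume_image()].
#' @param x,y In-plane world coordinates in mm.
#' @param z Axial world coordinate in mm; default is the central slice.
#' @return HU value (scalar).
#' @export
probe_hu <- function(vol, x, y, z = NULL) {
  i <- which.min(abs(vol_y(vol) - y))
  j <- which.min(abs(vol_x(vol) - x))
  k <- if (is.null(z)) ceiling(dim(vol$voxels)[3] / 2) else which.min(abs(vol_z(vol) - z))
  vol$voxels[i, j, k]
}

#' Render one axial slice as a ggplot
#'
#' @param vol A [volume_image()].
#' @param slice Slice index; default the central slice.
#' @param hu_limits Optional length-2 HU window for the fill scale.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = NULL, hu_limits = NULL) {
  k <- slice %||% ceiling(dim(vol$voxels)[3] / 2)
  df <- expand.grid(y = vol_y(vol), x = vol_x(vol))
  df$hu <- as.vector(vol$voxels[, , k])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = hu_limits,
                                 oob = scales_squish) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "HU")
}

## minimal squish so we need not depend on scales directly
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}
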