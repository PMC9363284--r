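## Rasterization of phantom geometries into HU volumes.
##
## Boundary voxels get area-weighted partial-volume mixtures computed on a
## supersampled sub-grid: each voxel is split into supersampling^2 sub-cells
## and a region's coverage fraction is the fraction of sub-cell centers it
## contains. Regions are painted in order (body first, inserts on top) over
## an air background.

## odd voxel count covering extent_mm at pitch v, so one voxel center sits
## exactly on the axis
odd_count <- function(extent_mm, v) {
  n <- ceiling(extent_mm / v)
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

## paint all regions active on one plane; xs, ys are voxel-center coords
rasterize_plane <- function(regions, xs, ys, v, ss, bg_hu = -1000) {
  nr <- length(ys); nc <- length(xs)
  hu <- matrix(bg_hu, nr, nc)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * v   # sub-cell center offsets
  for (reg in regions) {
    bb <- region_bbox(reg)
    if (is.null(bb)) {
      j1 <- 1L; j2 <- nc; i1 <- 1L; i2 <- nr
    } else {
      j1 <- match(TRUE, xs >= bb[1] - v); j2 <- nc - match(TRUE, rev(xs) <= bb[2] + v) + 1L
      i1 <- match(TRUE, ys >= bb[3] - v); i2 <- nr - match(TRUE, rev(ys) <= bb[4] + v) + 1L
      if (is.na(j1) || is.na(i1) || j1 > j2 || i1 > i2) next
    }
    xf <- rep(xs[j1:j2], each = ss) + off
    yf <- rep(ys[i1:i2], each = ss) + off
    ind <- switch(reg$shape,
      circle = outer((yf - reg$center[2])^2, (xf - reg$center[1])^2, "+") <=
        reg$radius^2,
      rect = outer(abs(yf - reg$center[2]) <= reg$half_h,
                   abs(xf - reg$center[1]) <= reg$half_w, "&"),
      halfplane = outer(reg$normal[2] * (yf - reg$point[2]),
                        reg$normal[1] * (xf - reg$point[1]), "+") >= 0,
      all = matrix(TRUE, length(yf), length(xf)))
    frac <- block_mean(ind + 0, ss)
    sub <- hu[i1:i2, j1:j2, drop = FALSE]
    hu[i1:i2, j1:j2] <- sub * (1 - frac) + reg$hu * frac
  }
  hu
}

## core: rasterize onto an explicit grid (voxel-center coordinate vectors)
rasterize_grid <- function(geometry, xs, ys, zs, v, supersampling) {
  ## identical active-region sets share one rasterized plane
  active <- vapply(zs, function(z) {
    paste(which(vapply(geometry$regions,
                       function(r) z >= r$zmin && z <= r$zmax, logical(1))),
          collapse = ",")
  }, character(1))
  vox <- array(0, c(length(ys), length(xs), length(zs)))
  for (sig in unique(active)) {
    idx <- as.integer(strsplit(sig, ",")[[1]])
    plane <- rasterize_plane(geometry$regions[idx], xs, ys, v, supersampling)
    for (k in which(active == sig)) vox[, , k] <- plane
  }
  vox
}

#' Rasterize a phantom geometry into an HU volume
#'
#' Produces a noise-free HU volume of the phantom on a grid of the requested
#' voxel size. Voxels fully inside a region carry its nominal HU; voxels
#' straddling a boundary carry the area-weighted mixture from a supersampled
#' sub-grid. The surrounding medium is air (-1000 HU).
#'
#' @param geometry A `phantom_geometry` (see [phantom_uniformity()],
#'   [phantom_hu_inserts()], [phantom_contrast_box()],
#'   [phantom_slanted_edge()]).
#' @param voxel_size In-plane voxel pitch in mm.
#' @param supersampling Sub-cells per voxel edge for the partial-volume
#'   model (default 8).
#' @param n_slices Number of axial slices (default 5, centered on the
#'   phantom's mid-height).
#' @param slice_thickness Slice pitch in mm; defaults to `voxel_size`.
#' @param margin_mm Air margin around the phantom (ignored when `grid_mm`
#'   or `window` is given).
#' @param grid_mm Optional explicit in-plane grid extent (x, y) in mm; an
#'   extent smaller than the phantom is rejected with a sizing error.
#' @param window Optional sub-window: `list(center = c(x, y), size = c(w, h))`
#'   in mm, e.g. to rasterize only a patch at the phantom rim.
#' @return A [volume_image()] with the geometry recorded in `$provenance`.
#' @export
rasterize_phantom <- function(geometry, voxel_size, supersampling = 8L,
                              n_slices = 5L, slice_thickness = NULL,
                              margin_mm = 6, grid_mm = NULL, window = NULL) {
  check_that(inherits(geometry, "phantom_geometry"), "`geometry` must be a phantom_geometry.",
             "phantomqc_bad_geometry")
  check_that(voxel_size > 0, "`voxel_size` must be > 0.", "phantomqc_bad_spacing")
  check_that(supersampling >= 1, "`supersampling` must be >= 1.", "phantomqc_bad_arg")
  v <- voxel_size
  dz <- slice_thickness %||% v
  if (!is.null(window)) {
    nx <- odd_count(window$size[1], v); ny <- odd_count(window$size[2], v)
    cx <- window$center[1]; cy <- window$center[2]
  } else {
    ext <- if (!is.null(grid_mm)) {
      check_that(all(grid_mm >= geometry$extent_mm),
                 sprintf("Requested grid (%g x %g mm) is smaller than the phantom (%g x %g mm).",
                         grid_mm[1], grid_mm[2], geometry$extent_mm[1], geometry$extent_mm[2]),
                 "phantomqc_grid_too_small")
      grid_mm
    } else geometry$extent_mm + 2 * margin_mm
    nx <- odd_count(ext[1], v); ny <- odd_count(ext[2], v)
    cx <- 0; cy <- 0
  }
  xs <- cx + (seq_len(nx) - (nx + 1) / 2) * v
  ys <- cy + (seq_len(ny) - (ny + 1) / 2) * v
  zc <- geometry$height_mm / 2
  zs <- zc + (seq_len(n_slices) - (n_slices + 1) / 2) * dz
  vox <- rasterize_grid(geometry, xs, ys, zs, v, as.integer(supersampling))
  vol <- volume_image(vox, c(v, v, dz), origin = c(xs[1], ys[1], zs[1]),
                      modality = "SIM")
  vol$provenance <- list(kind = geometry$kind, voxel_size = v,
                         supersampling = as.integer(supersampling))
  vol
}
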