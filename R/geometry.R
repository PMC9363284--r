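## Phantom geometries.
##
## A phantom_geometry is an ordered list of regions painted over an air
## background: the outer body first, then the inserts (which must lie
## strictly inside the body). Regions are z-extruded shapes: a circle,
## rectangle or half-plane cross-section active over [zmin, zmax] mm.
## The phantom axis is the world z-axis through (0, 0).

region <- function(shape, material, hu, center = c(0, 0),
                   radius = NULL, half_w = NULL, half_h = NULL,
                   normal = NULL, point = NULL,
                   zmin = -Inf, zmax = Inf) {
  list(shape = shape, material = material, hu = hu, center = center,
       radius = radius, half_w = half_w, half_h = half_h,
       normal = normal, point = point, zmin = zmin, zmax = zmax)
}

new_phantom_geometry <- function(kind, regions, extent_mm, height_mm,
                                 cupping_radius, materials) {
  structure(
    list(kind = kind, regions = regions, extent_mm = extent_mm,
         height_mm = height_mm, cupping_radius = cupping_radius,
         materials = materials),
    class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("<phantom_geometry> kind '%s', %d region(s), extent %.0f x %.0f mm, height %.0f mm\n",
              x$kind, length(x$regions), x$extent_mm[1], x$extent_mm[2], x$height_mm))
  invisible(x)
}

#' Uniformity phantom: homogeneous cylinder
#'
#' A homogeneous cylinder (default 140 mm diameter, 85 mm height) used for
#' uniformity measurement and, at its rim, for edge-method MTF estimation.
#'
#' @param diameter_mm,height_mm Outer dimensions in mm.
#' @param material Body material name (default PMMA).
#' @param materials Material library, see [material_library()].
#' @return A `phantom_geometry`.
#' @export
phantom_uniformity <- function(diameter_mm = 140, height_mm = 85,
                               material = "pmma",
                               materials = material_library()) {
  R <- diameter_mm / 2
  body <- region("circle", material, material_hu(material, materials),
                 center = c(0, 0), radius = R, zmin = 0, zmax = height_mm)
  new_phantom_geometry("uniformity_cylinder", list(body),
                       extent_mm = c(diameter_mm, diameter_mm),
                       height_mm = height_mm, cupping_radius = R,
                       materials = materials)
}

#' HU-accuracy phantom: cylinder with four attenuation inserts
#'
#' A cylinder (default 50 mm diameter, 70 mm height) holding four 15 mm
#' inserts — air, PMMA, PVC and PTFE — at 12, 3, 6 and 9 o'clock on a
#' common pitch circle, used to measure Hounsfield-unit accuracy.
#'
#' @param diameter_mm,height_mm Outer body dimensions in mm.
#' @param insert_diameter_mm,insert_height_mm Insert dimensions in mm.
#' @param pitch_radius_mm Distance of insert centers from the axis.
#' @param body_material Body material name.
#' @param materials Material library.
#' @return A `phantom_geometry`.
#' @export
phantom_hu_inserts <- function(diameter_mm = 50, height_mm = 70,
                               insert_diameter_mm = 15, insert_height_mm = 30,
                               pitch_radius_mm = 14,
                               body_material = "pmma",
                               materials = material_library()) {
  R <- diameter_mm / 2
  r <- insert_diameter_mm / 2
  check_that(pitch_radius_mm + r < R,
             "Inserts must lie strictly inside the outer boundary.",
             "phantomqc_bad_geometry")
  z0 <- (height_mm - insert_height_mm) / 2
  z1 <- z0 + insert_height_mm
  ins <- function(mat, cx, cy)
    region("circle", mat, material_hu(mat, materials), center = c(cx, cy),
           radius = r, zmin = z0, zmax = z1)
  body <- region("circle", body_material, material_hu(body_material, materials),
                 center = c(0, 0), radius = R, zmin = 0, zmax = height_mm)
  regions <- list(
    body,
    ins("air", 0, pitch_radius_mm),          # 12 o'clock
    ins("pmma", pitch_radius_mm, 0),         # 3 o'clock
    ins("pvc", 0, -pitch_radius_mm),         # 6 o'clock
    ins("ptfe", -pitch_radius_mm, 0))        # 9 o'clock
  new_phantom_geometry("hu_insert_cylinder", regions,
                       extent_mm = c(diameter_mm, diameter_mm),
                       height_mm = height_mm, cupping_radius = R,
                       materials = materials)
}

#' Low-contrast phantom: water box with tissue rods
#'
#' A water-filled box (default 83 x 85 mm cross-section) holding five 30 mm
#' electron-density rods: two breast and two liver rods near the corners and
#' one trabecular-bone rod on the axis. Used for CNR, CNRD and LCV.
#'
#' Rod packing is tight by construction (five 30 mm rods barely fit the box),
#' so the water channels left for background ROIs run along the edge
#' midspans, not the corners.
#'
#' @param width_mm,depth_mm In-plane outer dimensions (x, y) in mm.
#' @param height_mm Axial extent of the water volume in mm.
#' @param rod_diameter_mm,rod_height_mm Rod dimensions in mm.
#' @param materials Material library (rod HUs are presets, see
#'   [material_library()]).
#' @return A `phantom_geometry`.
#' @export
phantom_contrast_box <- function(width_mm = 83, depth_mm = 85, height_mm = 60,
                                 rod_diameter_mm = 30, rod_height_mm = 50,
                                 materials = material_library()) {
  r <- rod_diameter_mm / 2
  z0 <- (height_mm - rod_height_mm) / 2
  z1 <- z0 + rod_height_mm
  rod <- function(mat, cx, cy)
    region("circle", mat, material_hu(mat, materials), center = c(cx, cy),
           radius = r, zmin = z0, zmax = z1)
  body <- region("rect", "water", material_hu("water", materials),
                 center = c(0, 0), half_w = width_mm / 2, half_h = depth_mm / 2,
                 zmin = 0, zmax = height_mm)
  cx <- width_mm / 2 - r - 0.5   # 26 mm for the default box: 0.5 mm wall gap
  cy <- depth_mm / 2 - r - 0.5   # 27 mm
  regions <- list(
    body,
    rod("breast", -cx,  cy),
    rod("liver",   cx,  cy),
    rod("bone",     0,   0),
    rod("liver",  -cx, -cy),
    rod("breast",  cx, -cy))
  new_phantom_geometry("contrast_box", regions,
                       extent_mm = c(width_mm, depth_mm),
                       height_mm = height_mm,
                       cupping_radius = sqrt((width_mm / 2)^2 + (depth_mm / 2)^2),
                       materials = materials)
}

#' Slanted-edge test scene
#'
#' A half-plane step between two materials, tilted by a small angle from the
#' column (y) axis — the standard scene for slanted-edge MTF estimation with
#' an exactly known system response.
#'
#' @param angle_deg Edge tilt from the column axis in degrees (positive tilts
#'   the high side); small angles (2-6 degrees) give the classic sub-pixel
#'   phase coverage.
#' @param size_mm In-plane scene extent (x, y) in mm.
#' @param hu_low,hu_high HU on either side of the edge; the high side is
#'   x > 0 at y = 0.
#' @param height_mm Axial extent in mm.
#' @return A `phantom_geometry` of kind `slanted_edge`.
#' @export
phantom_slanted_edge <- function(angle_deg = 3, size_mm = c(26, 26),
                                 hu_low = 0, hu_high = 1000, height_mm = 10) {
  th <- angle_deg * pi / 180
  ## edge line passes through (0,0) with direction (sin th, cos th);
  ## outward normal of the high side is (cos th, -sin th)
  bg <- region("all", "low", hu_low, zmin = 0, zmax = height_mm)
  hi <- region("halfplane", "high", hu_high, point = c(0, 0),
               normal = c(cos(th), -sin(th)), zmin = 0, zmax = height_mm)
  g <- new_phantom_geometry("slanted_edge", list(bg, hi),
                            extent_mm = size_mm, height_mm = height_mm,
                            cupping_radius = NA_real_,
                            materials = material_library())
  g$angle_deg <- angle_deg
  g
}

## point-in-region indicator on vectors of world coords (same length)
region_indicator <- function(reg, x, y) {
  switch(reg$shape,
    circle = (x - reg$center[1])^2 + (y - reg$center[2])^2 <= reg$radius^2,
    rect = abs(x - reg$center[1]) <= reg$half_w & abs(y - reg$center[2]) <= reg$half_h,
    halfplane = reg$normal[1] * (x - reg$point[1]) + reg$normal[2] * (y - reg$point[2]) >= 0,
    all = rep(TRUE, length(x)),
    abort(paste0("Unknown region shape: ", reg$shape), class = "phantomqc_bad_geometry"))
}

## in-plane bounding box of a region (mm), or NULL for unbounded shapes
region_bbox <- function(reg) {
  switch(reg$shape,
    circle = c(reg$center[1] - reg$radius, reg$center[1] + reg$radius,
               reg$center[2] - reg$radius, reg$center[2] + reg$radius),
    rect = c(reg$center[1] - reg$half_w, reg$center[1] + reg$half_w,
             reg$center[2] - reg$half_h, reg$center[2] + reg$half_h),
    NULL)
}
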