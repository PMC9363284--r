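#' Built-in material library
#'
#' Nominal Hounsfield units for the materials of the three QA phantoms:
#' the four attenuation inserts (air, PMMA, PVC, PTFE), water, and the
#' three electron-density rods (breast, liver, trabecular bone 200 mg/cc
#' hydroxyapatite). Rod HUs are configurable presets — electron-density
#' rods are specified by density, not HU, so these defaults are plausible
#' values for a ~100 kVp beam and are never used as ground truth.
#'
#' @param breast_hu,liver_hu,bone_hu Override the rod HU presets.
#' @return A tibble with columns `material` and `nominal_hu`.
#' @export
#' @examples
#' material_library()
material_library <- function(breast_hu = -45, liver_hu = 60, bone_hu = 280) {
  tibble(
    material = c("air", "pmma", "pvc", "ptfe", "water",
                 "breast", "liver", "bone"),
    nominal_hu = c(-1000, 120, -120, 990, 0,
                   breast_hu, liver_hu, bone_hu))
}

material_hu <- function(name, materials = material_library()) {
  i <- match(name, materials$material)
  check_that(!anyNA(i), paste0("Unknown material: ", paste(name[is.na(i)], collapse = ", ")),
             "phantomqc_unknown_material")
  materials$nominal_hu[i]
}
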