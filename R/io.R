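## Reading and writing HU volumes. Two formats are supported:
##
## * NIfTI (.nii / .nii.gz) via RNifti — spacing travels in pixdim, HU are
##   stored as 32-bit floats.
## * Multi-page TIFF + JSON sidecar — TIFF carries no physical spacing and
##   the float encoder is only defined on [0, 1], so the sidecar manifest
##   records spacing, origin and the slope/intercept rescale back to HU.
##   The sidecar is required on read, never guessed.
##
## Axis convention: voxels are (row, col, slice); NIfTI files store
## (x = col, y = row, z = slice) so an independent NIfTI reader sees the
## same grid dimensions.

sidecar_path <- function(path) paste0(path, ".json")

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  if (dir.exists(path))
    abort("DICOM series input is not supported by this build; convert to NIfTI or TIFF+sidecar.",
          class = "phantomqc_unsupported_format")
  abort(paste0("Cannot infer a supported format from: ", path),
        class = "phantomqc_unsupported_format")
}

#' Write an HU volume
#'
#' Persists the voxel grid together with its spacing and HU calibration so
#' that [read_volume()] round-trips. TIFF output always gets a JSON sidecar
#' manifest (`<path>.json`) holding spacing, origin and the slope/intercept
#' mapping from stored samples back to HU.
#'
#' @param vol A [volume_image()].
#' @param path Output path (`.nii`, `.nii.gz`, `.tif`/`.tiff`).
#' @param format Override the format inferred from the extension
#'   (`"nifti"` or `"tiff"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  check_that(is_volume_image(vol), "`vol` must be a volume_image.", "phantomqc_bad_volume")
  format <- format %||% guess_format(path)
  if (format == "nifti") {
    arr <- aperm(vol$voxels, c(2, 1, 3))   # (x, y, z)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (format == "tiff") {
    lo <- min(vol$voxels); hi <- max(vol$voxels)
    slope <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(vol$voxels)[3]),
                    function(k) (vol$voxels[, , k] - lo) / slope)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    manifest <- list(format_version = 1L,
                     spacing_mm = vol$spacing, origin_mm = vol$origin,
                     modality = vol$modality,
                     rescale_slope = slope, rescale_intercept = lo)
    jsonlite::write_json(manifest, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  } else {
    abort(paste0("Unsupported format: ", format), class = "phantomqc_unsupported_format")
  }
  invisible(path)
}

#' Read an HU volume
#'
#' Returns voxels in HU with the spacing taken from the file metadata (NIfTI
#' pixdim) or the sidecar manifest (TIFF). A missing or non-positive spacing
#' is an explicit error — spacing is never silently defaulted. Stored
#' samples are mapped to HU through the recorded slope/intercept rescale.
#'
#' @param path Input path (`.nii`, `.nii.gz`, `.tif`/`.tiff`).
#' @param format Override the inferred format.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, format = NULL) {
  check_that(file.exists(path), paste0("File not found: ", path),
             "phantomqc_io_error")
  format <- format %||% guess_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    check_that(length(pd) >= 3 && all(is.finite(pd[1:3])) && all(pd[1:3] > 0),
               "NIfTI file does not record a positive voxel spacing.",
               "phantomqc_missing_spacing")
    arr <- array(as.numeric(img), dim(img))
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    volume_image(aperm(arr, c(2, 1, 3)), pd[1:3], modality = "NIfTI")
  } else if (format == "tiff") {
    sc <- sidecar_path(path)
    check_that(file.exists(sc),
               paste0("TIFF carries no spacing: sidecar manifest missing (", sc, ")."),
               "phantomqc_missing_spacing")
    man <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (key in c("spacing_mm", "rescale_slope", "rescale_intercept"))
      check_that(!is.null(man[[key]]), paste0("Sidecar manifest lacks '", key, "'."),
                 "phantomqc_missing_spacing")
    check_that(all(man$spacing_mm > 0), "Sidecar spacing must be positive.",
               "phantomqc_missing_spacing")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vox <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      vox[, , k] <- pg * man$rescale_slope + man$rescale_intercept
    }
    volume_image(vox, man$spacing_mm,
                 origin = man$origin_mm %||% NULL,
                 modality = man$modality %||% "TIFF")
  } else {
    abort(paste0("Unsupported format: ", format), class = "phantomqc_unsupported_format")
  }
}
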