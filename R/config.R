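## Study configuration: which protocols to analyze, with what ROI layouts
## and options. YAML or JSON, strict schema — unknown keys are errors so a
## typo never silently falls back to a default.

config_schema <- list(
  top = c("protocols", "rois", "options"),
  protocol = c("label", "ctdi_vol", "voxel_mm", "device"),
  roi = c("shape", "center", "diameter_mm", "width_mm", "height_mm", "label"),
  options = c("slices", "compute_cnrd", "seed", "blur_fwhm", "noise_sd_ref",
              "ctdi_ref", "cupping_amplitude"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  check_that(length(bad) == 0,
             sprintf("Unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                     where, paste(bad, collapse = ", ")),
             "phantomqc_config_error")
}

parse_roi_entry <- function(x, where) {
  check_keys(x, config_schema$roi, where)
  shape <- x$shape %||% "circle"
  check_that(!is.null(x$center) && length(x$center) == 2,
             sprintf("%s: `center` must be [x, y] in mm.", where),
             "phantomqc_config_error")
  if (shape == "circle") {
    check_that(!is.null(x$diameter_mm), sprintf("%s: circle needs `diameter_mm`.", where),
               "phantomqc_config_error")
    roi_circle(unlist(x$center), x$diameter_mm, x$label %||% NULL)
  } else if (shape == "rect") {
    check_that(!is.null(x$width_mm) && !is.null(x$height_mm),
               sprintf("%s: rect needs `width_mm` and `height_mm`.", where),
               "phantomqc_config_error")
    roi_rect(unlist(x$center), x$width_mm, x$height_mm, x$label %||% NULL)
  } else {
    abort(sprintf("%s: unknown ROI shape '%s'.", where, shape),
          class = "phantomqc_config_error")
  }
}

#' Load and validate a study configuration
#'
#' Reads a YAML or JSON study configuration and returns it fully defaulted
#' and validated. Required section: `protocols` (list of `label`,
#' `ctdi_vol`, `voxel_mm`, `device`). Optional: `rois` (named ROI
#' definitions in mm world coordinates) and `options`. Unknown keys anywhere
#' are errors naming the offending key; a protocol without a positive
#' `ctdi_vol` is an error when CNRD is requested.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return `list(protocols = tibble, rois = named list of roi_spec,
#'   options = list)`.
#' @export
load_study_config <- function(path) {
  check_that(file.exists(path), paste0("Config file not found: ", path),
             "phantomqc_io_error")
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  check_that(is.list(cfg) && !is.null(cfg$protocols) && length(cfg$protocols) > 0,
             "Config is missing the required `protocols` section.",
             "phantomqc_config_error")
  check_keys(cfg, config_schema$top, "config")
  opts <- cfg$options %||% list()
  check_keys(opts, config_schema$options, "options")
  opts$compute_cnrd <- opts$compute_cnrd %||% TRUE
  opts$slices <- opts$slices %||% 5L
  protocols <- purrr::imap_dfr(cfg$protocols, function(p, i) {
    where <- sprintf("protocols[%s]", i)
    check_keys(p, config_schema$protocol, where)
    check_that(!is.null(p$label), sprintf("%s: `label` is required.", where),
               "phantomqc_config_error")
    check_that(!is.null(p$voxel_mm) && p$voxel_mm > 0,
               sprintf("%s: positive `voxel_mm` is required.", where),
               "phantomqc_config_error")
    ctdi <- p$ctdi_vol %||% NA_real_
    if (isTRUE(opts$compute_cnrd))
      check_that(!is.na(ctdi) && ctdi > 0,
                 sprintf("%s: `ctdi_vol` must be > 0 when CNRD is requested.", where),
                 "phantomqc_config_error")
    tibble(label = p$label, ctdi_vol = as.numeric(ctdi),
           voxel_mm = as.numeric(p$voxel_mm), device = p$device %||% "sim")
  })
  check_that(!anyDuplicated(paste(protocols$device, protocols$label)),
             "Duplicate (device, label) protocol entries.", "phantomqc_config_error")
  rois <- purrr::imap(cfg$rois %||% list(), function(r, nm)
    parse_roi_entry(r, sprintf("rois$%s", nm)))
  list(protocols = protocols, rois = rois, options = opts)
}
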