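## One analyzed acquisition = one protocol report (one column of a
## dose-neutral comparison table); several reports = the comparison table.

metric_row_order <- c("ctdi_mgy", "uniformity_hu", "uniformity_abs_hu",
                      "cnr", "cnrd", "lcv",
                      "air_hu", "ptfe_hu", "pmma_hu", "pvc_hu",
                      "air_err_pct", "ptfe_err_pct", "pmma_err_pct", "pvc_err_pct",
                      "mtf10_lpmm", "mtf50_lpmm")

## reporting precision: one decimal, half away from zero, except the
## small-magnitude ratios (LCV) and frequencies (MTF), reported at two
report_digits <- function(metric) {
  ifelse(metric %in% c("lcv", "mtf10_lpmm", "mtf50_lpmm"), 2L, 1L)
}

default_geometries <- function() {
  list(uniformity = phantom_uniformity(),
       hu = phantom_hu_inserts(),
       contrast = phantom_contrast_box())
}

#' Analyze one acquisition into a protocol report
#'
#' Runs every metric whose phantom volume is present: uniformity (and the
#' rim MTF) from the uniformity phantom, HU accuracy from the insert
#' phantom, CNR/CNRD/LCV from the contrast phantom. Metrics whose phantom
#' is absent are reported as missing (NA), not zero; a failing metric is
#' recorded as an error message without voiding the rest of the column.
#'
#' @param volumes Named list of [volume_image()]s; recognized names are
#'   `uniformity`, `hu`, `contrast` (any subset).
#' @param protocol A [protocol_meta()].
#' @param geometries Named list of `phantom_geometry`s matching `volumes`;
#'   defaults to the three study phantoms.
#' @param layouts Optional named list overriding the default ROI layouts
#'   (`uniformity`, `hu`, `contrast`).
#' @param slices Slice selection passed to the ROI metrics.
#' @param mtf Logical: measure the rim MTF from the uniformity phantom
#'   (default TRUE).
#' @return A `protocol_report`.
#' @export
analyze_acquisition <- function(volumes, protocol, geometries = default_geometries(),
                                layouts = list(), slices = NULL, mtf = TRUE) {
  check_that(inherits(protocol, "protocol_meta"), "`protocol` must be a protocol_meta.",
             "phantomqc_bad_arg")
  vals <- stats::setNames(as.list(rep(NA_real_, length(metric_row_order))),
                          metric_row_order)
  vals$ctdi_mgy <- protocol$ctdi_vol
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if (!is.null(volumes$uniformity)) {
    u <- grab("uniformity", {
      lay <- layouts$uniformity %||% default_uniformity_layout(geometries$uniformity)
      compute_uniformity(volumes$uniformity, lay, slices)
    })
    if (!is.null(u)) {
      vals$uniformity_hu <- u$uniformity
      vals$uniformity_abs_hu <- u$uniformity_abs
    }
    if (mtf) {
      mt <- grab("mtf", {
        R <- geometries$uniformity$cupping_radius
        ## tall enough along the rim that the sagitta spans a full pixel
        ## (sub-pixel phase coverage for the radial ESF)
        roi <- roi_rect(c(R, 0), width_mm = 10, height_mm = 16)
        measure_mtf(volumes$uniformity, roi, circle_center = c(0, 0))
      })
      if (!is.null(mt)) {
        vals$mtf50_lpmm <- attr(mt, "mtf50")
        vals$mtf10_lpmm <- attr(mt, "mtf10")
      }
    }
  }
  if (!is.null(volumes$hu)) {
    h <- grab("hu_accuracy", {
      lay <- layouts$hu %||% default_hu_layout(geometries$hu)
      analyze_hu_phantom(volumes$hu, lay, geometry = geometries$hu, slices = slices)
    })
    if (!is.null(h)) {
      for (i in seq_len(nrow(h))) {
        vals[[paste0(h$material[i], "_hu")]] <- h$measured_hu[i]
        vals[[paste0(h$material[i], "_err_pct")]] <- h$error_percent[i]
      }
    }
  }
  if (!is.null(volumes$contrast)) {
    ct <- grab("contrast", {
      lay <- layouts$contrast %||% default_contrast_layout(geometries$contrast)
      analyze_contrast_phantom(volumes$contrast, lay, ctdi_vol = protocol$ctdi_vol,
                               slices = slices)
    })
    if (!is.null(ct)) {
      vals$cnr <- ct$cnr
      vals$cnrd <- ct$cnrd
      vals$lcv <- ct$lcv
    }
  }
  structure(list(protocol = protocol, values = vals, errors = errors),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> %s / %s (CTDIvol %s mGy)\n",
              x$protocol$device, x$protocol$label,
              format(x$protocol$ctdi_vol)))
  print(tidy(x), n = Inf)
  if (length(x$errors))
    cat("errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.protocol_report <- function(x, ...) {
  tibble(metric = metric_row_order,
         value = as.numeric(unlist(x$values[metric_row_order])))
}

#' @export
glance.protocol_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(device = x$protocol$device, protocol = x$protocol$label),
    as_tibble(x$values))
}

## serialized form: values rounded by the reporting convention
report_serial <- function(report) {
  v <- tidy(report)
  v$value <- round_half_away(v$value, report_digits(v$metric))
  list(device = report$protocol$device,
       protocol = report$protocol$label,
       metrics = stats::setNames(as.list(v$value), v$metric),
       errors = report$errors)
}

#' Write a protocol report as JSON
#'
#' Values are rounded at serialization only (one decimal, half away from
#' zero; two decimals for LCV and MTF frequencies); in-memory reports stay
#' at full precision. Missing metrics serialize as null.
#'
#' @param report A `protocol_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_serial(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Build a dose-neutral comparison table
#'
#' Metric rows in the standard report order, one column per (device,
#' protocol). Every cell is copied from a protocol report — no cell is
#' derived twice.
#'
#' @param reports List of `protocol_report`s (at least one); duplicate
#'   (device, protocol) pairs are an error.
#' @return A `comparison_table` tibble: `metric` plus one column per
#'   report, named `<device>.<protocol>`.
#' @export
build_comparison <- function(reports) {
  check_that(length(reports) >= 1, "Need at least one report.", "phantomqc_bad_arg")
  cols <- vapply(reports, function(r) paste(r$protocol$device, r$protocol$label,
                                            sep = "."), character(1))
  check_that(!anyDuplicated(cols),
             "Duplicate (device, protocol) labels among the reports.",
             "phantomqc_duplicate_report")
  out <- tibble(metric = metric_row_order)
  for (i in seq_along(reports)) {
    v <- tidy(reports[[i]])
    out[[cols[i]]] <- round_half_away(v$value, report_digits(v$metric))
  }
  class(out) <- c("comparison_table", class(out))
  out
}

#' Export a comparison table
#'
#' @param ct A `comparison_table` from [build_comparison()].
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"markdown"`. Missing cells export as
#'   empty (CSV), null (JSON) or "n/a" (markdown).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(ct, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(ct), path, row.names = FALSE, na = "")
  } else if (format == "json") {
    jsonlite::write_json(as.data.frame(ct), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    cols <- names(ct)
    fmt_cell <- function(x) ifelse(is.na(x), "n/a", format(x, trim = TRUE))
    lines <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
               vapply(seq_len(nrow(ct)), function(i) {
                 cells <- c(ct$metric[i],
                            vapply(cols[-1], function(cn) fmt_cell(ct[[cn]][i]),
                                   character(1)))
                 paste0("| ", paste(cells, collapse = " | "), " |")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a CSV comparison table
#'
#' @param path CSV written by [write_comparison()].
#' @return A `comparison_table` tibble.
#' @export
read_comparison <- function(path) {
  df <- as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
  class(df) <- c("comparison_table", class(df))
  df
}
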