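#' Published three-scanner sinus-study metrics
#'
#' The image-quality metrics reported for the dose-neutral three-scanner
#' sinus-imaging comparison (dental CBCT, extremity CBCT, MDCT at
#' ultra-low-dose, low-dose and default protocols): CTDIvol, uniformity,
#' CNR, CNRD, LCV, measured insert HU with error percentages, and
#' MTF10/MTF50. Bundled as a plain-text table; its CNR/CTDI and measured-HU
#' columns are the inputs of the worked-example arithmetic (recomputing
#' CNRD and HU error% from the printed values).
#'
#' Known quirks of the printed table are preserved as printed: three CNRD
#' cells (mdct ULD 25.3, dental_cbct LD 15.9, extremity_cbct DF 9.8) are
#' not consistent with the CNR and CTDI printed beside them, and the MDCT
#' ULD CTDI appears as 0.5 here but 0.6 in the protocol listing. These
#' cells are reported, not reconciled.
#'
#' @return A tibble, one row per (device, protocol).
#' @export
study_metrics <- function() {
  path <- system.file("extdata", "sinus_study_metrics.csv", package = "phantomqc",
                      mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
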