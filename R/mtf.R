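## Slanted-edge MTF estimation: identify the edge, project pixels onto the
## edge normal to build a supersampled edge spread function, differentiate
## to the line spread function, and take the normalized Fourier transform.
## This is the standard ISO-12233-style realization of the edge method;
## every knob (bin width, window factor, frequency cutoff) is exposed.

## sub-image of one slice covered by a rectangular ROI, with mm coordinates
edge_subimage <- function(vol, roi, slice) {
  check_that(roi$shape == "rect", "Edge ROI must be rectangular.", "phantomqc_bad_roi")
  check_that(roi_in_bounds(vol, roi), "ROI extends beyond the image bounds.",
             "phantomqc_roi_oob")
  xs <- vol_x(vol); ys <- vol_y(vol)
  jj <- which(abs(xs - roi$center[1]) <= roi$width / 2)
  ii <- which(abs(ys - roi$center[2]) <= roi$height / 2)
  list(m = vol$voxels[ii, jj, slice], x = xs[jj], y = ys[ii])
}

#' Fit a straight edge inside a rectangular ROI
#'
#' Finds the sub-pixel half-maximum crossing of each image line across the
#' edge, then fits a least-squares line through the crossings. The ROI must
#' contain exactly one approximately straight high-contrast boundary
#' spanning at least 20 pixels across.
#'
#' @param vol A [volume_image()].
#' @param roi A rectangular [roi_rect()] containing the edge.
#' @param slice Slice index (default: central slice).
#' @return An `edge_roi`: intercept/slope of the edge line (x = a + b y, in
#'   mm), `angle_deg` from the column (y) axis, residual RMS in pixels, and
#'   the polarity (+1 if the high side lies at larger signed distance).
#' @export
detect_edge <- function(vol, roi, slice = NULL) {
  px <- vol_pixel_mm(vol)
  slice <- slice %||% ceiling(dim(vol$voxels)[3] / 2)
  sub <- edge_subimage(vol, roi, slice)
  m <- sub$m; xmm <- sub$x; ymm <- sub$y
  ## orient so the edge runs along rows (crossings found along x):
  ## the across-edge axis is the one whose mean profile has the larger swing
  swing_x <- diff(range(colMeans(m)))
  swing_y <- diff(range(rowMeans(m)))
  transposed <- swing_y > swing_x
  if (transposed) { m <- t(m); tmp <- xmm; xmm <- ymm; ymm <- tmp }
  check_that(ncol(m) >= 20, "Edge ROI must span at least 20 pixels across the edge.",
             "phantomqc_bad_roi")
  cross <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- m[i, ]
    half <- (mean(head(p, 4)) + mean(tail(p, 4))) / 2
    if (abs(mean(tail(p, 4)) - mean(head(p, 4))) < 1e-9) next
    dpos <- which.max(abs(diff(p)))
    win <- max(1, dpos - 3):min(length(p) - 1, dpos + 3)
    s <- p - half
    j <- win[which(s[win] * s[win + 1] <= 0 & s[win] != s[win + 1])]
    if (length(j) == 0) next
    j <- j[which.min(abs(j - dpos))]
    frac <- s[j] / (s[j] - s[j + 1])
    cross[i] <- xmm[j] + frac * (xmm[j + 1] - xmm[j])
  }
  ok <- !is.na(cross)
  check_that(mean(ok) >= 0.8, "No edge crossing found in more than 20% of lines.",
             "phantomqc_no_edge")
  fit <- stats::lm(cross[ok] ~ ymm[ok])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  rms_px <- sqrt(mean(stats::resid(fit)^2)) / px
  check_that(rms_px <= 1, "Edge is not straight (residual RMS exceeds 1 pixel).",
             "phantomqc_no_edge")
  hi_right <- mean(m[, ncol(m)]) > mean(m[, 1])
  structure(
    list(a = a, b = b, angle_deg = atan(b) * 180 / pi,
         residual_rms_px = rms_px, polarity = if (hi_right) 1 else -1,
         transposed = transposed, roi = roi, slice = slice),
    class = "edge_roi")
}

#' @export
print.edge_roi <- function(x, ...) {
  cat(sprintf("<edge_roi> angle %.2f deg, residual RMS %.3f px, high side %s\n",
              x$angle_deg, x$residual_rms_px, if (x$polarity > 0) "+" else "-"))
  invisible(x)
}

new_esf_curve <- function(df, bin_width_mm, pixel_mm) {
  structure(df, class = c("esf_curve", class(df)),
            bin_width_mm = bin_width_mm, pixel_mm = pixel_mm)
}

## complete the bin sequence: empty bins (sub-pixel phases the edge
## geometry did not cover) are linearly interpolated and marked n = 0.
## A gap wider than one pixel near the edge means the sampling genuinely
## failed and is an error, not something to interpolate away.
fill_esf_gaps <- function(ib, value, n, w, pixel_mm) {
  full <- seq(min(ib), max(ib))
  pos <- (full + 0.5) * w
  miss <- !(full %in% ib)
  if (any(miss)) {
    ctr_gap <- miss & abs(pos) <= 2
    if (any(ctr_gap)) {
      rc <- rle(ctr_gap)
      check_that(max(rc$lengths[rc$values]) * w <= pixel_mm + 1e-9,
                 "Empty central ESF bins after pooling (gap wider than one pixel).",
                 "phantomqc_esf_gap")
    }
    v <- approx((ib + 0.5) * w, value, xout = pos, rule = 2)$y
    nn <- integer(length(full)); nn[!miss] <- n
    tibble(x = pos, value = v, n = nn)
  } else {
    tibble(x = pos, value = value, n = n)
  }
}

#' Sample the edge spread function across a fitted edge
#'
#' Projects every ROI pixel onto the edge normal (signed distance in mm,
#' high side positive) and pools the pixels into bins of `bin_width` pixel
#' fractions — the slanted-edge supersampling that recovers the presampled
#' ESF. Edge angles below 1 degree leave sub-pixel phases uncovered and
#' trigger a warning.
#'
#' @param vol A [volume_image()].
#' @param edge An `edge_roi` from [detect_edge()].
#' @param bin_width Bin width as a fraction of a pixel, in (0, 1]
#'   (default 0.1).
#' @return An `esf_curve` tibble: `x` (mm), `value` (HU, bin mean), `n`.
#' @export
sample_esf <- function(vol, edge, bin_width = 0.1) {
  check_that(bin_width > 0 && bin_width <= 1, "`bin_width` must be in (0, 1].",
             "phantomqc_bad_arg")
  if (abs(edge$angle_deg) < 1)
    warn("Edge angle below 1 degree: sub-pixel bins may be unevenly covered.")
  px <- vol_pixel_mm(vol)
  sub <- edge_subimage(vol, edge$roi, edge$slice)
  m <- sub$m; xmm <- sub$x; ymm <- sub$y
  if (edge$transposed) { m <- t(m); tmp <- xmm; xmm <- ymm; ymm <- tmp }
  X <- matrix(rep(xmm, each = nrow(m)), nrow(m))
  Y <- matrix(rep(ymm, times = ncol(m)), nrow(m))
  d <- edge$polarity * (X - (edge$a + edge$b * Y)) / sqrt(1 + edge$b^2)
  w <- bin_width * px
  idx <- floor(as.vector(d) / w)
  agg <- tapply(as.vector(m), idx, mean)
  cnt <- tapply(as.vector(m), idx, length)
  ib <- as.integer(names(agg))
  o <- order(ib)
  df <- fill_esf_gaps(ib[o], as.numeric(agg)[o], as.integer(cnt)[o], w, px)
  new_esf_curve(df, w, px)
}

new_lsf_curve <- function(df, bin_width_mm, pixel_mm, window) {
  structure(df, class = c("lsf_curve", class(df)),
            bin_width_mm = bin_width_mm, pixel_mm = pixel_mm, window = window)
}

#' Differentiate an ESF to the line spread function
#'
#' Central finite difference of the binned ESF. A Hann window centered on
#' the LSF peak (full width = `window_factor` times the LSF
#' full-width-at-quarter-maximum) is computed and stored alongside the raw
#' derivative; it is applied by [lsf_to_mtf()] to suppress noise-floor bias
#' in the spectrum tails.
#'
#' @param esf An `esf_curve` from [sample_esf()] (at least 3 bins, strictly
#'   increasing positions).
#' @param window_factor Hann window width in units of the LSF FWQM
#'   (default 4).
#' @return An `lsf_curve` tibble: `x` (mm), `value` (HU/mm, unwindowed),
#'   `window` (Hann weights).
#' @export
differentiate_to_lsf <- function(esf, window_factor = 4) {
  check_that(nrow(esf) >= 3, "ESF needs at least 3 bins.", "phantomqc_bad_arg")
  x <- esf$x; v <- esf$value
  check_that(all(diff(x) > 0), "ESF positions must be strictly increasing.",
             "phantomqc_bad_arg")
  h <- attr(esf, "bin_width_mm")
  n <- length(v)
  xi <- x[2:(n - 1)]
  lsf <- (v[3:n] - v[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  ## window placement must not lock onto a noise spike in the tails: find
  ## the peak on a pixel-width running mean, restricted to near the edge
  ## (the ESF coordinate is centered on the fitted crossing)
  px <- attr(esf, "pixel_mm") %||% h
  k <- max(1L, round(px / h))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- if (k > 1) as.numeric(stats::filter(abs(lsf), rep(1 / k, k), sides = 2)) else abs(lsf)
  sm[is.na(sm)] <- 0
  near <- abs(xi) <= max(2 * px, min(5, max(abs(xi))))
  if (!any(near)) near <- rep(TRUE, length(xi))
  pk <- which(near)[which.max(sm[near])]
  qm <- sm >= sm[pk] / 4
  lo <- pk; while (lo > 1 && qm[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < length(lsf) && qm[hi + 1]) hi <- hi + 1
  fwqm <- (hi - lo + 1) * h
  W <- window_factor * fwqm
  u <- (xi - xi[pk]) / W
  win <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
  new_lsf_curve(tibble(x = xi, value = lsf, window = win),
                h, attr(esf, "pixel_mm"),
                window = list(type = "hann", center_mm = xi[pk],
                              width_mm = W, fwqm_mm = fwqm,
                              factor = window_factor))
}

new_mtf_curve <- function(df, mtf50, mtf10, nyquist, pixel_mm, bin_width_mm) {
  structure(df, class = c("mtf_curve", class(df)),
            mtf50 = mtf50, mtf10 = mtf10, nyquist = nyquist,
            pixel_mm = pixel_mm, bin_width_mm = bin_width_mm)
}

#' Normalized MTF from a line spread function
#'
#' Magnitude of the discrete Fourier transform of the windowed LSF divided
#' by its zero-frequency component, so MTF(0) = 1 exactly. Frequencies are
#' in line pairs per mm from the physical bin width; the curve is reported
#' up to the detector sampling's Nyquist frequency by default (the slanted
#' edge itself resolves beyond it — raise `f_max` to look there).
#'
#' @param lsf An `lsf_curve` from [differentiate_to_lsf()].
#' @param pixel_mm Detector pixel pitch in mm (default: recorded in the
#'   LSF).
#' @param f_max Frequency cutoff in lp/mm; default `1 / (2 * pixel_mm)`.
#' @param pad_to Zero-padded DFT length (frequency-axis interpolation).
#' @return An `mtf_curve` tibble (`frequency`, `modulation`) with `mtf50`
#'   and `mtf10` attributes (NA with a warning if a level is not reached
#'   before the cutoff).
#' @export
lsf_to_mtf <- function(lsf, pixel_mm = NULL, f_max = NULL, pad_to = 4096) {
  pixel_mm <- pixel_mm %||% attr(lsf, "pixel_mm")
  h <- attr(lsf, "bin_width_mm")
  y <- lsf$value * lsf$window
  area <- sum(y)
  check_that(abs(area) > 1e-12 * max(abs(lsf$value), 1e-300),
             "Windowed LSF has zero area; MTF is undefined.",
             "phantomqc_zero_lsf")
  n <- max(pad_to, length(y))
  sp <- Mod(fft(c(y, rep(0, n - length(y)))))
  mtf <- sp / abs(area)
  f <- (seq_len(n) - 1) / (n * h)
  f_max <- f_max %||% (1 / (2 * pixel_mm))
  keep <- f <= f_max + 1e-12
  df <- tibble(frequency = f[keep], modulation = mtf[keep])
  curve <- new_mtf_curve(df, NA_real_, NA_real_, 1 / (2 * pixel_mm), pixel_mm, h)
  attr(curve, "mtf50") <- mtf_percentile(curve, 0.5, quiet = TRUE)
  attr(curve, "mtf10") <- mtf_percentile(curve, 0.1, quiet = TRUE)
  curve
}

#' Frequency at which the MTF first falls to a level
#'
#' First downward crossing of `level`, linearly interpolated between the
#' adjacent frequency samples. If the curve never falls to the level inside
#' its reported range the result is NA ("beyond the reported range"), never
#' an extrapolation.
#'
#' @param curve An `mtf_curve`.
#' @param level Modulation level in (0, 1), e.g. 0.5 or 0.1.
#' @param quiet Suppress the beyond-range warning.
#' @return Frequency in lp/mm, or NA.
#' @export
mtf_percentile <- function(curve, level, quiet = FALSE) {
  check_that(level > 0 && level < 1, "`level` must be in (0, 1).", "phantomqc_bad_arg")
  f <- curve$frequency; m <- curve$modulation
  check_that(m[1] >= level - 1e-9,
             "MTF does not start above the requested level.", "phantomqc_bad_arg")
  below <- which(m <= level + 1e-12)
  below <- below[below > 1]
  if (length(below) == 0) {
    if (!quiet) warn(sprintf(
      "MTF stays above %.0f%% up to the reported cutoff (%.3g lp/mm): level beyond Nyquist.",
      100 * level, max(f)))
    return(NA_real_)
  }
  i <- below[1]
  if (abs(m[i] - level) < 1e-12) return(f[i])
  f[i - 1] + (level - m[i - 1]) * (f[i] - f[i - 1]) / (m[i] - m[i - 1])
}

#' End-to-end MTF measurement from an edge
#'
#' Composition of [detect_edge()], [sample_esf()], [differentiate_to_lsf()]
#' and [lsf_to_mtf()] with their defaults. For an edge that is actually a
#' circular phantom rim, pass the circle center: pixels are then projected
#' radially (distance to the detected rim radius), which removes the
#' curvature sagitta that a straight-line fit would fold into the ESF.
#'
#' @param vol A [volume_image()].
#' @param roi Rectangular [roi_rect()] containing the edge.
#' @param slice Slice index (default central).
#' @param bin_width ESF bin width in pixel fractions (default 0.1).
#' @param window_factor Hann window factor (default 4).
#' @param f_max Frequency cutoff; default the detector Nyquist.
#' @param circle_center Optional `c(x, y)` mm center of a circular edge.
#' @return An `mtf_curve` with `mtf50`/`mtf10` attributes.
#' @export
measure_mtf <- function(vol, roi, slice = NULL, bin_width = 0.1,
                        window_factor = 4, f_max = NULL,
                        circle_center = NULL) {
  esf <- if (is.null(circle_center)) {
    edge <- detect_edge(vol, roi, slice)
    sample_esf(vol, edge, bin_width)
  } else {
    sample_esf_radial(vol, roi, circle_center, slice, bin_width)
  }
  lsf <- differentiate_to_lsf(esf, window_factor)
  lsf_to_mtf(lsf, f_max = f_max)
}

## ESF against radial distance from a known circle center: for a curved rim
## the signed coordinate is r - r_edge, with r_edge the half-maximum
## crossing of the coarse radial profile
sample_esf_radial <- function(vol, roi, center, slice = NULL, bin_width = 0.1) {
  px <- vol_pixel_mm(vol)
  slice <- slice %||% ceiling(dim(vol$voxels)[3] / 2)
  sub <- edge_subimage(vol, roi, slice)
  X <- matrix(rep(sub$x, each = length(sub$y)), length(sub$y))
  Y <- matrix(rep(sub$y, times = length(sub$x)), length(sub$y))
  r <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  ## coarse profile at pixel pitch to locate the rim
  ci <- floor(as.vector(r) / px)
  prof <- tapply(as.vector(sub$m), ci, mean)
  rr <- (as.integer(names(prof)) + 0.5) * px
  o <- order(rr); rr <- rr[o]; prof <- as.numeric(prof)[o]
  half <- (mean(head(prof, 3)) + mean(tail(prof, 3))) / 2
  s <- prof - half
  j <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
  check_that(length(j) >= 1, "No rim crossing found in the radial profile.",
             "phantomqc_no_edge")
  j <- j[1]
  r_edge <- rr[j] + s[j] / (s[j] - s[j + 1]) * (rr[j + 1] - rr[j])
  pol <- if (mean(head(prof, 3)) > mean(tail(prof, 3))) -1 else 1
  d <- pol * (as.vector(r) - r_edge)
  w <- bin_width * px
  idx <- floor(d / w)
  agg <- tapply(as.vector(sub$m), idx, mean)
  cnt <- tapply(as.vector(sub$m), idx, length)
  ib <- as.integer(names(agg))
  o <- order(ib)
  ## sub-pixel phase coverage comes from the rim sagitta across the ROI:
  ## warn when the ROI is too short along the rim to span a full pixel
  sag <- (diff(range(sub$y))^2 / 8) / max(r_edge, 1e-6)
  if (sag < px)
    warn("Rim ROI spans less than one pixel of sagitta: sub-pixel bins may be interpolated.")
  fill_esf_gaps(ib[o], as.numeric(agg)[o], as.integer(cnt)[o], w, px) |>
    new_esf_curve(w, px)
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %d samples to %.3g lp/mm; MTF50 %.3g, MTF10 %.3g lp/mm\n",
              nrow(x), max(x$frequency), attr(x, "mtf50"), attr(x, "mtf10")))
  invisible(x)
}

#' @export
tidy.mtf_curve <- function(x, ...) tibble(frequency = x$frequency, modulation = x$modulation)

#' @export
glance.mtf_curve <- function(x, ...) {
  tibble(mtf50 = attr(x, "mtf50"), mtf10 = attr(x, "mtf10"),
         nyquist = attr(x, "nyquist"))
}

#' @export
autoplot.mtf_curve <- function(object, ...) {
  df <- tidy(object)
  g <- glance(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$modulation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.5, 0.1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "spatial frequency (lp/mm)", y = "MTF")
  if (!is.na(g$mtf50))
    p <- p + ggplot2::geom_vline(xintercept = c(g$mtf50, g$mtf10),
                                 linetype = "dotted", colour = "steelblue")
  p
}

#' Export an MTF curve as a two-column CSV
#'
#' @param curve An `mtf_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mtf_csv <- function(curve, path) {
  write.csv(tidy(curve), path, row.names = FALSE)
  invisible(path)
}
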