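## small shared numerics

#' Round half away from zero
#'
#' Reported image-quality values follow the common "half away from zero"
#' rounding convention rather than R's banker's rounding, so that e.g.
#' 10.15 prints as 10.2 and -10.15 as -10.2.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the reporting
#'   convention used throughout the package).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.25, -0.25), 1)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## mean of f x f blocks of a matrix whose dims are multiples of f
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m) / f
  nc <- ncol(m) / f
  out <- matrix(0, nr, nc)
  for (i in seq_len(f)) {
    ri <- seq(i, by = f, length.out = nr)
    for (j in seq_len(f)) {
      out <- out + m[ri, seq(j, by = f, length.out = nc)]
    }
  }
  out / (f * f)
}

## Gaussian FWHM <-> sigma (FWHM = 2 sqrt(2 ln 2) sigma)
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

## analytic system MTF of the simulator: Gaussian PSF x square pixel aperture
#' Analytic modulation transfer function of the simulated system
#'
#' Closed form for the in-plane MTF realized by the simulator: a Gaussian
#' point-spread function of the stated full width at half maximum multiplied
#' by the square pixel-aperture transfer function \eqn{sinc(\pi f \Delta)}.
#' Used as the ground-truth oracle in edge-method recovery tests.
#'
#' @param f Spatial frequency in line pairs per mm.
#' @param blur_fwhm Gaussian PSF full width at half maximum in mm.
#' @param pixel_mm Detector pixel pitch in mm (0 disables the aperture term).
#' @return MTF values in `[0, 1]`.
#' @export
analytic_system_mtf <- function(f, blur_fwhm, pixel_mm = 0) {
  sigma <- fwhm_to_sigma(blur_fwhm)
  g <- exp(-2 * pi^2 * sigma^2 * f^2)
  if (pixel_mm > 0) {
    x <- pi * f * pixel_mm
    s <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
    g <- g * abs(s)
  }
  g
}

## stopifnot-style check with a classed error
check_that <- function(ok, msg, class) {
  if (!ok) abort(msg, class = class)
  invisible(TRUE)
}
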