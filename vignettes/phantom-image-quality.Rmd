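---
title: "Phantom-based CT/CBCT image quality: models, metrics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based CT/CBCT image quality: models, metrics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomqc)
```

## The problem

Comparing CT-type scanners objectively requires scanning the same physical
phantoms on every device and reducing the images to a handful of numbers:
image uniformity, Hounsfield-unit (HU) accuracy, contrast-to-noise ratio
(CNR), low-contrast visibility (LCV) and the modulation transfer function
(MTF). Because different protocols deliver different doses, contrast
metrics are additionally dose-normalized: CNRD = CNR / sqrt(CTDIvol)
removes the sqrt(dose) dependence of quantum noise, so protocols at
different dose levels become directly comparable.

phantomqc implements this analysis pipeline, and — because the physical
phantom scans cannot ship with the software — a synthetic phantom
simulator whose degradations have known ground truth, so every metric is
validated by parameter recovery rather than by eye.

## The three phantoms

* **Uniformity cylinder**: a homogeneous ⌀140 × 85 mm cylinder (PMMA by
  default). Used for the five-ROI uniformity metric and, at its rim, for
  the edge-method MTF.
* **HU-insert cylinder**: ⌀50 × 70 mm with four ⌀15 × 30 mm inserts: air
  (−1000 HU), PMMA (+120), PVC (−120), PTFE (+990). Used for HU accuracy.
* **Contrast box**: an 83 × 85 mm water-filled box holding five ⌀30 × 50 mm
  electron-density rods (two breast, two liver, one trabecular bone
  200 mg/cc HA). Used for CNR, CNRD and LCV.

The rods are specified by electron density (0.99, 1.07, 1.16 g/cc), not by
HU; the simulator uses configurable presets (breast −45, liver +60, bone
+280 HU — plausible values for a ~100 kVp beam) and the validation suite
never treats them as physical truth, only as simulation ground truth.

Rod packing is tight by construction: five 30 mm rods barely fit the box
(corner rods at (±26, ±27) mm leave sub-millimetre wall gaps), which means
the corners hold almost no free water. The default water and background
ROIs therefore sit in the edge-midspan water channels at (0, ±36) mm, the
only pockets that keep ≥ 5 mm clearance from every rod surface.

## Metric definitions

With `m` a ROI mean and `s` a ROI standard deviation (sample SD, n−1):

* **Uniformity** = mean over the four peripheral ROIs of
  (m_center − m_peripheral). The layout is one central ⌀10 mm ROI plus four
  ⌀10 mm ROIs at 3, 6, 9, 12 o'clock, 10 mm in from the rim (the radial
  placement is a convention; it is configurable). The signed value is
  primary; since cupping makes it negative while QA reports usually quote
  magnitudes, the absolute variant (mean |difference|) is reported
  alongside.
* **HU error%** = 100 · |measured − nominal| / |nominal| per insert,
  reported at one decimal. Undefined for water (nominal 0), where the
  absolute offset in HU is reported instead.
* **CNR** = |m_bone − m_water| / s_background; a noise-free image makes
  this undefined (an explicit error, never infinity).
* **CNRD** = CNR / sqrt(CTDIvol in mGy).
* **LCV** = 2 |m_water − m_breast| / (s_water + s_breast).

Reported values are rounded half away from zero at serialization only —
one decimal for HU-scale quantities and ratios, two for LCV and MTF
frequencies; in-memory values stay at full precision. ROIs require at
least 25 member voxels (degenerate SD guard); metrics pool the central
5-slice slab by default.

## Edge-method MTF

The spatial response is estimated from a high-contrast edge in the
standard slanted-edge fashion:

1. **Edge fit** (`detect_edge`): sub-pixel half-maximum crossing of every
   image line across the edge, followed by a least-squares line fit.
   Residual RMS above one pixel, or missing crossings in more than 20% of
   lines, reject the ROI.
2. **ESF** (`sample_esf`): every ROI pixel is projected onto the edge
   normal and pooled into bins of 0.1 pixel — the slant provides the
   sub-pixel phase diversity. Isolated empty bins are interpolated; a gap
   wider than one pixel near the edge is an error. Edges shallower than 1°
   trigger a coverage warning.
3. **LSF** (`differentiate_to_lsf`): central finite difference. A Hann
   window centered on the LSF peak, of full width 4 × the LSF
   full-width-at-quarter-maximum (configurable), is recorded and applied
   before the transform to suppress noise-floor bias. The peak is located
   on a pixel-width-smoothed |LSF| restricted to the neighbourhood of the
   fitted edge, so a noise spike in the tails cannot capture the window.
4. **MTF** (`lsf_to_mtf`): |DFT| of the windowed LSF divided by its
   zero-frequency component, so MTF(0) = 1 exactly. Frequencies are in
   lp/mm from the physical bin width; the curve is reported up to the
   detector Nyquist 1/(2Δ) by default. The slanted edge genuinely resolves
   beyond Nyquist; raise `f_max` to look there (needed e.g. for a blur-free
   edge whose aperture-limited MTF50 lies above Nyquist).
5. **MTF50/MTF10** (`mtf_percentile`): first downward crossing, linearly
   interpolated; a level not reached inside the reported range returns NA
   with a warning, never an extrapolation.

For a *circular* phantom rim the straight-line fit would fold the rim
sagitta into the ESF. `measure_mtf(..., circle_center =)` instead projects
pixels radially (distance to the detected rim radius), which removes the
curvature exactly. The flip side is that phase diversity now comes from the
sagitta itself: the default rim ROI is 16 mm along the rim so that its
sagitta spans at least one pixel; shorter ROIs fall back to interpolated
bins with a warning.

**Known bias.** Windowing reshapes the LSF core slightly: with the default
4 × FWQM Hann window a pure Gaussian spectrum is biased by roughly 2%
(MTF50 reads ~2–5% high). This is the usual noise-robustness/accuracy
trade-off of the edge method; widening the window (`window_factor = 8`)
removes most of the bias on clean data, and the recovery suite bounds the
total error at < 5% RMS against the closed form.

## The simulator

`simulate_acquisition()` composes four stages with known ground truth:

1. **Rasterization** (`rasterize_phantom`): geometry painted over air at
   the requested voxel pitch; boundary voxels get area-weighted
   partial-volume mixtures from an 8× supersampled sub-grid. This is a
   counting model: coverage is quantized at one part in 64, i.e. a
   worst-case half-sub-cell bias for axis-aligned boundaries, while
   aggregate areas are conserved to < 0.1% — adequate for ROI metrics, and
   for edges it realizes the exact square pixel aperture in aggregate.
2. **System blur** (`apply_system_blur`): isotropic in-plane Gaussian of
   stated FWHM. Inside `simulate_acquisition` the blur is applied on a
   `render_scale`-finer grid (default 4×) and then block-averaged to
   detector voxels: a discrete Gaussian applied directly at detector
   resolution aliases badly once sigma is sub-pixel, whereas the fine-grid
   route makes the realized system MTF the closed-form product
   exp(−2π²σ²f²) · sinc(πfΔ) to within ~1%. The standalone
   `apply_system_blur` (erf-integrated taps, edge-renormalized) is accurate
   when FWHM is not much below the voxel pitch.
3. **Cupping** (`apply_cupping`): radially parabolic bias
   b(r) = A (1 − (r/R)²) inside the phantom, zero outside — the minimal
   one-parameter smooth model of the scatter-driven center-to-edge bias of
   cone-beam systems. Negative A depresses the center (cupping), positive A
   is capping. For the box phantom R is the circumscribed radius.
4. **Noise** (`add_dose_scaled_noise`): zero-mean white Gaussian with
   SD = noise_sd_ref · sqrt(ctdi_ref / CTDI). The sqrt-dose law makes CNRD
   dose-invariant by construction — which is exactly the property the
   recovery suite then verifies end-to-end. All randomness flows from one
   integer seed; identical seeds give bit-identical volumes.

Default model parameters (`acquisition_model()`) are chosen once to put
the simulated metrics on the scale of a dental CBCT column of the study
the phantoms come from: blur FWHM 0.7 mm (MTF50 ≈ 0.6 lp/mm at 0.4 mm
voxels), noise 28 HU at 1 mGy (CNR ≈ 7 at 0.5 mGy with the +280 HU bone
rod), cupping −60 HU (uniformity magnitude ≈ 40 HU). They are presets, not
fits.

What the simulator deliberately does *not* model: projection-domain
physics (beam hardening, scatter transport), correlated noise texture
(CT noise is white here because the metrics consume only means and SDs),
anisotropic or anthropomorphic geometry, and partial volume along z
(slices are thin relative to every structure of interest). Passing
recovery tests therefore validates the *analysis* under these idealized
degradations; they say nothing about, e.g., noise-texture effects on real
scans.

## Numerical choices and degenerate inputs

* Voxel membership of a circular ROI is by voxel-center inclusion; ROI
  bounds are checked against the grid, and n < 25 voxels is an error.
* Rounding: half away from zero, applied only at report serialization.
* Blur kernels truncate at 4σ with row renormalization, so constants (and
  fully-interior region means) are conserved exactly.
* Zero blur, zero amplitude and zero noise are exact identities.
* Zero LSF area, noise-free CNR, both-SDs-zero LCV, water nominal in
  error% — all explicit classed errors rather than NaN/Inf.
* Missing report metrics serialize as null/"n/a", never as zero.
* TIFF volumes are stored as 32-bit floats mapped to [0, 1] with
  slope/intercept and spacing in a JSON sidecar (the TIFF float writer is
  only defined on the unit interval, and TIFF itself carries no spacing —
  a missing sidecar is an error, never a guessed default). NIfTI carries
  spacing in pixdim. DICOM series are not read by this build; convert to
  NIfTI or TIFF + sidecar first.

## Validation suite sizes

The shipped tests and the acceptance script use problem sizes chosen for a
single CPU: 26 mm edge scenes at 0.2/0.4 mm voxels for the six-case MTF
recovery (< 5% RMS vs the closed form up to MTF10), the full contrast box
at 0.4 mm with 3 slices and 10 seeds per dose for CNRD invariance
(constant within 5% across 0.5/1.4/3.7 mGy while CNR grows as sqrt(dose)),
the uniformity phantom at 0.8 mm against a brute-force pixel-sum oracle
(< 0.5 HU), 20 random scenes for the exact ROI-statistics oracle, and
byte-identity of two end-to-end `simulate` + `analyze` runs at a fixed
seed.

## A worked example

```{r, eval = FALSE}
model <- acquisition_model(seed = 7L)
protocol <- protocol_meta("ULD", ctdi_vol = 0.5, voxel_size = 0.4,
                          device = "dental_cbct")
geoms <- list(uniformity = phantom_uniformity(),
              hu = phantom_hu_inserts(),
              contrast = phantom_contrast_box())
vols <- lapply(geoms, simulate_acquisition, model = model,
               protocol = protocol)
report <- analyze_acquisition(vols, protocol)
tidy(report)
build_comparison(list(report))
```

The published metrics themselves (uniformity, CNR, LCV, MTF50/MTF10 of the
three scanners) require the physical phantom scans and are bundled only as
a printed table (`study_metrics()`); the package recomputes the arithmetic
that links its columns (CNRD from CNR and CTDI, error% from measured and
nominal HU) and validates everything else by simulation recovery.
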