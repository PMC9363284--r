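# Independent brute-force oracles: plain loops, no shared code with the
# package internals they check.

# mean/sd/n over a circular or rectangular ROI by looping voxels
oracle_roi_stats <- function(vol, roi, slices) {
  xs <- vol$origin[1] + (seq_len(dim(vol$voxels)[2]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing[2]
  vals <- c()
  for (k in slices) {
    for (i in seq_along(ys)) {
      for (j in seq_along(xs)) {
        inside <- if (roi$shape == "circle") {
          (xs[j] - roi$center[1])^2 + (ys[i] - roi$center[2])^2 <= (roi$diameter / 2)^2
        } else {
          abs(xs[j] - roi$center[1]) <= roi$width / 2 &&
            abs(ys[i] - roi$center[2]) <= roi$height / 2
        }
        if (inside) vals <- c(vals, vol$voxels[i, j, k])
      }
    }
  }
  m <- sum(vals) / length(vals)
  list(mean = m, sd = sqrt(sum((vals - m)^2) / (length(vals) - 1)), n = length(vals))
}

# coverage fraction of a disc over one voxel by point counting at 32x
oracle_disc_coverage <- function(x0, y0, v, cx, cy, radius, ss = 32L) {
  hits <- 0L
  for (a in seq_len(ss)) {
    for (b in seq_len(ss)) {
      px <- x0 + ((a - 0.5) / ss - 0.5) * v
      py <- y0 + ((b - 0.5) / ss - 0.5) * v
      if ((px - cx)^2 + (py - cy)^2 <= radius^2) hits <- hits + 1L
    }
  }
  hits / ss^2
}

# exact disc coverage of one voxel: analytic chord height integrated over
# fine vertical strips (error << any counting estimate)
oracle_disc_coverage_exact <- function(x0, y0, v, cx, cy, radius, N = 4096L) {
  xs <- x0 - v / 2 + (seq_len(N) - 0.5) * v / N
  d2 <- radius^2 - (xs - cx)^2
  g <- sqrt(pmax(d2, 0))
  yhi <- pmin(cy + g, y0 + v / 2)
  ylo <- pmax(cy - g, y0 - v / 2)
  cover <- ifelse(d2 > 0, pmax(yhi - ylo, 0), 0)
  sum(cover) * (v / N) / v^2
}

# mean parabolic cupping bias over a circular ROI by pixel summation
oracle_cupping_roi_mean <- function(vol, roi, amplitude, R) {
  xs <- vol$origin[1] + (seq_len(dim(vol$voxels)[2]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing[2]
  tot <- 0; n <- 0L
  for (i in seq_along(ys)) {
    for (j in seq_along(xs)) {
      if ((xs[j] - roi$center[1])^2 + (ys[i] - roi$center[2])^2 <= (roi$diameter / 2)^2) {
        r2 <- xs[j]^2 + ys[i]^2
        tot <- tot + amplitude * (1 - r2 / R^2)
        n <- n + 1L
      }
    }
  }
  tot / n
}

# small random-field volume for ROI statistics checks
random_scene <- function(seed, n = 48L, spacing = 0.8, slices = 3L) {
  set.seed(seed)
  volume_image(array(rnorm(n * n * slices, 50, 120), c(n, n, slices)), spacing)
}
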