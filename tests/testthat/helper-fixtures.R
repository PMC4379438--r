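# Shared fixtures: a compact transmission setup whose six LaB6-like rings all
# land on the detector.  256 x 256 px of 100 um at 50 mm puts the corner at
# 2-theta ~ 20 deg; lambda = 0.5 A reaches rings between ~7 and ~17 deg.

std_detector <- function(n = 256L) detector(c(n, n), 1e-4)

std_geometry <- function(n = 256L, rot1 = 0.01, rot2 = -0.004, rot3 = 0,
                         wavelength = 0.5e-10) {
  half <- n * 1e-4 / 2
  geometry(std_detector(n), dist = 0.05, poni1 = half, poni2 = half,
           rot1 = rot1, rot2 = rot2, rot3 = rot3, wavelength = wavelength)
}

std_calibrant <- function(wavelength = 0.5e-10)
  calibrant(c(4.1566, 2.9392, 2.3998, 2.0783, 1.8589, 1.6969),
            name = "LaB6-like-6", wavelength = wavelength)

# exact on-ring control points from the ground-truth geometry
exact_control_points <- function(geom, cal, n_per_ring = 72, jitter_tth = 0) {
  rings <- ring_angles(cal)
  n <- geom$detector$shape[1]
  pts <- NULL
  for (k in seq_along(rings)) {
    chi <- seq(-pi, pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
    tth <- rings[k] + if (jitter_tth > 0) runif(length(chi), -jitter_tth, jitter_tth) else 0
    yx <- azir:::ray_to_pixel(geom, tth, chi)
    ok <- is.finite(yx[, 1]) & yx[, 1] > 1 & yx[, 1] < n & yx[, 2] > 1 & yx[, 2] < n
    if (any(ok))
      pts <- rbind(pts, data.frame(ring = k, y = yx[ok, 1], x = yx[ok, 2]))
  }
  control_points(pts, geom$detector$shape)
}

# isotropic image from a smooth two-bump pattern; returns image + truth pattern
smooth_isotropic <- function(geom, npt = 600) {
  rng <- range(pixel_angles(geom, at = "centers")$tth)
  grid <- seq(rng[1], rng[2], length.out = npt)
  P <- 200 + 150 * exp(-((grid - mean(rng)) / (diff(rng) / 6))^2) +
       100 * exp(-((grid - rng[1] - diff(rng) * 0.75) / (diff(rng) / 9))^2)
  list(image = calcfrom1d(geom, grid, P, unit = "2th_rad"),
       grid = grid, pattern = P)
}

# render an isolated 2-D Gaussian peak (integrated, for subpixel truth tests)
render_gaussian <- function(ny, nx, y0, x0, sigma, amp = 100) {
  outer(amp^0 * exp(-0.5 * ((seq_len(ny) - y0) / sigma)^2),
        exp(-0.5 * ((seq_len(nx) - x0) / sigma)^2)) * amp
}
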