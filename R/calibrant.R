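#' Calibrant d-spacing bookkeeping
#'
#' A calibrant is an ordered list of lattice d-spacings (in angstroms) plus,
#' optionally, the wavelength of the experiment.  Together with Bragg's law
#' `2 theta_n = 2 asin(lambda / (2 d_n))` it yields the apertures of the
#' Debye-Scherrer cones used for geometry calibration.  Only d values are
#' stored, so regenerated ring images have equal integrated ring intensities.
#'
#' @param dspacing numeric vector of d values (angstroms, any order);
#'   duplicates are merged and values sorted descending.
#' @param name label.
#' @param wavelength metres; optional.
#' @return an object of class `"az_calibrant"`.
#' @examples
#' cal <- calibrant(c(4.1566, 2.9391, 2.3998), name = "LaB6-like",
#'                  wavelength = 1e-10)
#' ring_angles(cal) * 180 / pi
#' @export
calibrant <- function(dspacing, name = "user", wavelength = NULL) {
  d <- sort(unique(as.numeric(dspacing)), decreasing = TRUE)
  if (length(d) == 0 || any(!is.finite(d)) || any(d <= 0))
    stop("d-spacings must be positive finite values")
  if (!is.null(wavelength) && (!is.finite(wavelength) || wavelength <= 0))
    stop("wavelength must be positive when set")
  structure(list(name = name, dspacing = d, wavelength = wavelength),
            class = "az_calibrant")
}

#' @export
print.az_calibrant <- function(x, ...) {
  cat(sprintf("<az_calibrant '%s', %d d-spacings (%.4g .. %.4g A), lambda=%s>\n",
              x$name, length(x$dspacing), max(x$dspacing), min(x$dspacing),
              if (is.null(x$wavelength)) "unset" else sprintf("%.6g m", x$wavelength)))
  invisible(x)
}

#' Read a calibrant file
#'
#' Plain text, one d value in angstroms per line, `#` comments.
#' @param path file path; bundled fixtures: `system.file("extdata",
#'   "LaB6.D", package = "azir")` (also `CeO2.D`, `AgBh.D`).
#' @param name label (defaults to the file name).
#' @param wavelength metres; optional.
#' @export
read_calibrant <- function(path, name = NULL, wavelength = NULL) {
  if (!file.exists(path)) stop("calibrant file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  d <- suppressWarnings(as.numeric(lines))
  if (any(is.na(d))) stop("non-numeric d-spacing line in ", path)
  calibrant(d, name = if (is.null(name)) basename(path) else name,
            wavelength = wavelength)
}

#' Ring apertures of a calibrant
#'
#' `2 theta_n = 2 asin(lambda / (2 d_n))` for every d reachable at the given
#' wavelength, in ascending order.  Rings with `lambda > 2 d` are silently
#' excluded (a notice is logged when `options(azir.verbose = TRUE)`).
#'
#' @param cal an [calibrant()].
#' @param wavelength metres; defaults to the calibrant's own.
#' @return numeric vector of 2-theta values (radians), ascending.
#' @export
ring_angles <- function(cal, wavelength = cal$wavelength) {
  stopifnot(inherits(cal, "az_calibrant"))
  if (is.null(wavelength))
    stop("ring_angles needs a wavelength (set it on the calibrant or pass it)")
  x <- (wavelength * 1e10) / (2 * cal$dspacing)   # d in angstrom -> metres
  ok <- x <= 1
  if (any(!ok))
    .azir_log(sum(!ok), " ring(s) unreachable at this wavelength (lambda > 2d)")
  sort(2 * asin(x[ok]))
}

#' Caglioti resolution parameters
#'
#' Peak widths versus scattering angle follow
#' `FWHM^2(2 theta) = U tan^2(theta) + V tan(theta) + W` with `theta` half the
#' scattering angle and the FWHM expressed in the same unit as the radial
#' axis (radians of 2-theta throughout this package).
#'
#' @param U,V,W coefficients; `W` in squared radians.
#' @return an object of class `"az_caglioti"`.
#' @export
caglioti <- function(U = 0, V = 0, W = (4e-3)^2) {
  structure(list(U = U, V = V, W = W), class = "az_caglioti")
}

caglioti_fwhm <- function(cag, tth) {
  t <- tan(tth / 2)
  f2 <- cag$U * t^2 + cag$V * t + cag$W
  if (any(f2 <= 0)) stop("Caglioti FWHM^2 must stay positive over the rings used")
  sqrt(f2)
}

#' Regenerate a 2-D image from a 1-D pattern
#'
#' Assumes signal isotropy along the azimuth: every pixel takes the linearly
#' interpolated pattern value at its center's radial coordinate.  Pixels
#' outside the pattern support and masked pixels are set to 0.
#'
#' @param geom an [geometry()].
#' @param radial strictly increasing radial grid in `unit`.
#' @param intensity pattern values, same length as `radial`.
#' @param unit radial unit, one of `"2th_rad"`, `"2th_deg"`, `"q_nm^-1"`,
#'   `"q_A^-1"`, `"r_m"`, `"r_mm"`.
#' @param mask optional logical matrix, `TRUE` = masked.
#' @return numeric matrix `(Ny, Nx)`.
#' @export
calcfrom1d <- function(geom, radial, intensity, unit = "2th_rad", mask = NULL) {
  stopifnot(inherits(geom, "az_geometry"))
  if (length(radial) != length(intensity))
    stop("radial grid and intensity have different lengths")
  if (is.unsorted(radial, strictly = TRUE))
    stop("radial grid must be strictly increasing")
  ang <- pixel_angles(geom, at = "centers")
  coord <- unit_coordinate(ang, unit)
  img <- matrix(approx(radial, intensity, xout = as.vector(coord),
                       rule = 1)$y,
                nrow = geom$detector$shape[1])
  img[is.na(img)] <- 0
  m <- geom$detector$mask
  if (!is.null(mask)) m <- m | mask
  img[m] <- 0
  img
}

#' Synthetic calibration image with continuous rings
#'
#' Builds a 1-D pattern as a sum of unit-area Gaussian peaks at every
#' reachable ring aperture, with angle-dependent FWHM from the Caglioti
#' resolution function, rescales it so the tallest peak reaches `Imax`, and
#' renders it through [calcfrom1d()].  All rings have the same integrated
#' intensity.  Optional Poisson resampling gives a photon-counting image.
#'
#' @param cal an [calibrant()] with wavelength (or a geometry wavelength).
#' @param geom an [geometry()].
#' @param cag an [caglioti()] resolution description.
#' @param Imax approximate peak height (counts).
#' @param poisson_noise resample each pixel as Poisson with the noiseless
#'   image as mean.
#' @param seed integer seed used for the Poisson draw.
#' @param npt_pattern resolution of the intermediate 1-D pattern.
#' @param mask optional logical mask.
#' @return numeric matrix `(Ny, Nx)`; the noiseless pattern is attached as
#'   attributes `radial` (2-theta, radians) and `pattern`.
#' @export
fake_calibration_image <- function(cal, geom, cag = caglioti(), Imax = 1e4,
                                   poisson_noise = FALSE, seed = NULL,
                                   npt_pattern = 4096, mask = NULL) {
  wl <- if (!is.null(cal$wavelength)) cal$wavelength else geom$wavelength
  tth_rings <- ring_angles(cal, wl)
  ang <- pixel_angles(geom, at = "centers")
  lo <- min(ang$tth); hi <- max(ang$tth)
  grid <- seq(max(0, lo - 0.02), hi + 0.02, length.out = npt_pattern)
  fw <- caglioti_fwhm(cag, tth_rings)
  sig <- fw / (2 * sqrt(2 * log(2)))
  keep <- tth_rings > lo - 3 * fw & tth_rings < hi + 3 * fw
  if (!any(keep))
    stop("no calibrant ring falls inside the detector acceptance")
  pattern <- rep(0, npt_pattern)
  for (i in which(keep))
    pattern <- pattern + dnorm(grid, tth_rings[i], sig[i])
  pattern <- pattern * (Imax / max(pattern))
  img <- calcfrom1d(geom, grid, pattern, unit = "2th_rad", mask = mask)
  if (poisson_noise) {
    if (!is.null(seed)) set.seed(seed)
    img <- matrix(rpois(length(img), lambda = img) + 0.0, nrow = nrow(img))
  }
  attr(img, "radial") <- grid
  attr(img, "pattern") <- pattern
  img
}

#' Synthetic spotty-ring calibration image
#'
#' Emulates a coarse-grained calibrant: instead of continuous rings, each ring
#' carries `n_spots_per_ring` isotropically oriented Gaussian spots at random
#' azimuths.  Ground-truth subpixel spot centers are returned for peak-picking
#' tests.
#'
#' @inheritParams fake_calibration_image
#' @param n_spots_per_ring spots per ring.
#' @param spot_sigma spot width (pixels, isotropic Gaussian sigma).
#' @param Imax spot peak height (counts).
#' @param seed integer seed for spot azimuths (and Poisson noise if on).
#' @param margin spots closer than this (pixels) to the border are redrawn.
#' @return list with `image` (matrix) and `spots` (data.frame
#'   `ring`, `y`, `x`, `tth`), `ring` being the 1-based index into
#'   `ring_angles(cal)`.
#' @export
spotty_rings_image <- function(cal, geom, n_spots_per_ring = 20, spot_sigma = 2,
                               Imax = 1e3, poisson_noise = FALSE, seed = 1,
                               margin = 6) {
  wl <- if (!is.null(cal$wavelength)) cal$wavelength else geom$wavelength
  tth_rings <- ring_angles(cal, wl)
  det <- geom$detector
  ny <- det$shape[1]; nx <- det$shape[2]
  img <- matrix(0, ny, nx)
  set.seed(seed)
  spots <- NULL
  if (n_spots_per_ring > 0) {
    for (n in seq_along(tth_rings)) {
      chi <- runif(8 * n_spots_per_ring, -pi, pi)  # oversample, keep in-frame
      yx <- ray_to_pixel(geom, tth_rings[n], chi)
      ok <- which(is.finite(yx[, 1]) &
                  yx[, 1] > margin & yx[, 1] < ny - margin + 1 &
                  yx[, 2] > margin & yx[, 2] < nx - margin + 1)
      ok <- ok[seq_len(min(n_spots_per_ring, length(ok)))]
      if (length(ok) == 0) next
      spots <- rbind(spots, data.frame(ring = n, y = yx[ok, 1], x = yx[ok, 2],
                                       tth = tth_rings[n]))
    }
    if (!is.null(spots)) {
      half <- ceiling(4 * spot_sigma)
      for (s in seq_len(nrow(spots))) {
        y0 <- spots$y[s]; x0 <- spots$x[s]
        ii <- max(1, floor(y0) - half):min(ny, floor(y0) + half)
        jj <- max(1, floor(x0) - half):min(nx, floor(x0) + half)
        g <- Imax * outer(exp(-0.5 * ((ii - y0) / spot_sigma)^2),
                          exp(-0.5 * ((jj - x0) / spot_sigma)^2))
        img[ii, jj] <- img[ii, jj] + g
      }
    }
  }
  if (poisson_noise)
    img <- matrix(rpois(length(img), lambda = img) + 0.0, ny, nx)
  list(image = img,
       spots = if (is.null(spots))
         data.frame(ring = integer(), y = numeric(), x = numeric(), tth = numeric())
       else spots)
}
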