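#' Isotropic / Bragg separation
#'
#' Splits an image into an azimuthally symmetric component (amorphous halo,
#' powder rings) and the residual Bragg spots.  A 2-D azimuthal integration
#' is filtered along the azimuth chi with a percentile filter (default the
#' median, which ignores up to ~50% outlier azimuthal bins per ring); the
#' filtered 1-D pattern is re-projected through [calcfrom1d()] to give the
#' isotropic image, and `bragg = img - isotropic`, so
#' `isotropic + bragg == img` exactly on unmasked pixels.  Masked pixels are
#' zero in both outputs.
#'
#' @param img numeric matrix.
#' @param geom an [geometry()].
#' @param npt_rad,npt_azim 2-D integration grid (defaults 1024 x 512).
#' @param percentile percentile in `[0, 100]` taken over the nonempty
#'   azimuthal bins of each radial bin (linear interpolation definition).
#' @param mask optional logical matrix.
#' @param scheme splitting scheme for the 2-D integration (fullsplit gives
#'   the smoothest chi columns).
#' @return an `"az_separation"`: `isotropic`, `bragg` (matrices), `radial`,
#'   `pattern` (filtered 1-D pattern), `params`.
#' @export
separate <- function(img, geom, npt_rad = 1024, npt_azim = 512,
                     percentile = 50, mask = NULL, scheme = "fullsplit") {
  stopifnot(is.matrix(img), percentile >= 0, percentile <= 100)
  res <- integrate2d(img, geom, npt_rad = npt_rad, npt_azim = npt_azim,
                     unit = "2th_rad", scheme = scheme, mask = mask)
  pat <- apply(res$intensity, 1, function(row) {
    v <- row[is.finite(row)]
    if (length(v) == 0) NA_real_ else quantile(v, percentile / 100, type = 7,
                                               names = FALSE)
  })
  if (anyNA(pat)) {
    warning(sum(is.na(pat)), " radial bin(s) had no azimuthal coverage; ",
            "interpolated from neighbours")
    ok <- which(!is.na(pat))
    pat <- approx(res$radial[ok], pat[ok], xout = res$radial, rule = 2)$y
  }
  iso <- calcfrom1d(geom, res$radial, pat, unit = "2th_rad", mask = mask)
  bragg <- img - iso
  iso <- img - bragg   # re-subtraction keeps isotropic + bragg == img bit-exact
  m <- geom$detector$mask
  if (!is.null(mask)) m <- m | mask
  iso[m] <- 0
  bragg[m] <- 0
  structure(list(isotropic = iso, bragg = bragg,
                 radial = res$radial, pattern = pat,
                 params = list(npt_rad = npt_rad, npt_azim = npt_azim,
                               percentile = percentile, scheme = scheme)),
            class = "az_separation")
}

#' @export
print.az_separation <- function(x, ...) {
  cat(sprintf("<az_separation %d x %d, npt %d x %d, percentile %g>\n",
              nrow(x$isotropic), ncol(x$isotropic), x$params$npt_rad,
              x$params$npt_azim, x$params$percentile))
  invisible(x)
}

#' Frame score for serial-crystallography triage
#'
#' Sum of Bragg-component intensity exceeding `k` standard deviations of the
#' local isotropic level (sigma estimated per radial bin as the median
#' absolute deviation along chi, interpolated back to pixels).  Large scores
#' flag frames containing single-crystal diffraction.
#'
#' @param sep an `"az_separation"` from [separate()].
#' @param geom the same [geometry()].
#' @param k sigma multiplier (default 4).
#' @return list `score`, `n_pixels` (pixels above threshold), `k`.
#' @export
frame_score <- function(sep, geom, k = 4) {
  stopifnot(inherits(sep, "az_separation"))
  res2 <- integrate2d(sep$isotropic + sep$bragg, geom,
                      npt_rad = sep$params$npt_rad,
                      npt_azim = sep$params$npt_azim,
                      unit = "2th_rad", scheme = sep$params$scheme)
  madchi <- apply(res2$intensity, 1, function(row) {
    v <- row[is.finite(row)]
    if (length(v) < 4) NA_real_ else median(abs(v - median(v))) * 1.4826
  })
  ok <- which(!is.na(madchi))
  if (length(ok) < 2) return(list(score = 0, n_pixels = 0L, k = k))
  ang <- pixel_angles(geom, at = "centers")
  sig_px <- matrix(approx(res2$radial[ok], madchi[ok], xout = as.vector(ang$tth),
                          rule = 2)$y, nrow = nrow(sep$bragg))
  hot <- sep$bragg > k * sig_px & sep$bragg > 0
  list(score = sum(sep$bragg[hot]), n_pixels = sum(hot), k = k)
}

#' Subpixel image offset by phase correlation
#'
#' Computes the normalised cross-power spectrum of the two images, transforms
#' it back, and locates its peak; the peak is refined to subpixel accuracy by
#' the quadratic 3x3 refinement of [refine_subpixel()] applied to the
#' (circularly wrapped) correlation surface.  Returns the displacement
#' `(dy, dx)` of `img_b` relative to `img_a`: if `b` is `a` shifted down by
#' `s` rows, the result is `(s, 0)`.
#'
#' @param img_a,img_b equal-shape numeric matrices, non-constant.
#' @return numeric `(dy, dx)` in pixels.
#' @export
measure_offset <- function(img_a, img_b) {
  stopifnot(is.matrix(img_a), identical(dim(img_a), dim(img_b)))
  if (sd(as.vector(img_a)) == 0 || sd(as.vector(img_b)) == 0)
    stop("phase correlation is undefined for a constant image")
  fa <- fft(img_a)
  fb <- fft(img_b)
  cp <- Conj(fa) * fb
  mg <- Mod(cp)
  # frequencies with negligible cross-power carry only rounding-noise phase;
  # dropping them keeps the correlation peak clean for quadratic refinement
  keep <- mg > 1e-6 * max(mg)
  w <- cp * 0
  w[keep] <- cp[keep] / mg[keep]
  # a mild Gaussian spectral weight (sigma = 0.06 cycles/px): the whitened
  # spectrum of sharp images yields a Dirichlet-kernel peak on which a
  # parabola fit underestimates subpixel shifts; smoothing the peak removes
  # that bias without moving its position
  ny <- nrow(img_a); nx <- ncol(img_a)
  ky <- c(0:(ceiling(ny / 2) - 1), -(floor(ny / 2)):-1) / ny
  kx <- c(0:(ceiling(nx / 2) - 1), -(floor(nx / 2)):-1) / nx
  w <- w * outer(exp(-(ky / 0.06)^2 / 2), exp(-(kx / 0.06)^2 / 2))
  r <- Re(fft(w, inverse = TRUE)) / length(w)
  idx <- arrayInd(which.max(r), dim(r))
  ny <- nrow(r); nx <- ncol(r)
  # wrapped 3x3 neighbourhood around the peak
  wy <- (idx[1] - 2):(idx[1]) %% ny + 1
  wx <- (idx[2] - 2):(idx[2]) %% nx + 1
  patch <- r[wy, wx]
  d <- subpixel_delta2(patch)
  dy <- idx[1] - 1 + d$delta[1]
  dx <- idx[2] - 1 + d$delta[2]
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy = dy, dx = dx)
}

#' Validate a calibration by image regeneration
#'
#' Integrates the image with the candidate geometry, regenerates a synthetic
#' image from the 1-D pattern ([calcfrom1d()]), and measures the spatial
#' offset between original and regenerated image by phase correlation.  For a
#' correct calibration the offset magnitude is a fraction of a pixel; it
#' grows with PONI mislocalisation, so it quantifies the precision of the
#' PONI.
#'
#' @param img numeric matrix.
#' @param geom calibrated [geometry()].
#' @param npt radial bins for the intermediate integration.
#' @param mask optional logical matrix.
#' @return list `offset` (`(dy, dx)` px) and `magnitude` (px).
#' @export
validate_calibration <- function(img, geom, npt = 1024, mask = NULL) {
  res <- integrate1d(img, geom, npt = npt, unit = "2th_rad",
                     scheme = "fullsplit", mask = mask)
  ok <- is.finite(res$intensity)
  if (sum(ok) < 2) stop("too few nonempty bins to validate")
  pat <- approx(res$radial[ok], res$intensity[ok], xout = res$radial, rule = 2)$y
  regen <- calcfrom1d(geom, res$radial, pat, unit = "2th_rad", mask = mask)
  off <- measure_offset(img, regen)
  list(offset = off, magnitude = sqrt(sum(off^2)))
}
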