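#' Per-pixel corrections
#'
#' Produces the corrected signal
#' `(img - dark) / (flat * Omega * P)` on valid pixels, where
#' `Omega = cos^3(alpha)` is the relative solid angle (alpha = angle between
#' the pixel direction and the detector normal; `Omega = 1` at the PONI) and
#' `P = (1 + cos^2(tth) - f cos(2 chi) sin^2(tth)) / 2` is the Kahn-style
#' polarization factor for a polarization fraction `f`.  Pixels equal to the
#' `dummy` value (within `delta_dummy`) are dynamically masked.
#'
#' @param img numeric matrix, raw counts.
#' @param geom [geometry()] (needed for solid angle / polarization).
#' @param dark,flat optional matrices (dark current, flat field).
#' @param solid_angle apply the cos^3 solid-angle normalisation.
#' @param polarization_factor polarization fraction `f` in `[-1, 1]`, or
#'   `NULL` to skip.
#' @param mask optional logical matrix (static mask, `TRUE` = invalid).
#' @param dummy,delta_dummy dynamic-mask value and tolerance.
#' @return list with `signal` (corrected matrix) and `mask` (combined static
#'   + dynamic logical matrix).
#' @export
apply_corrections <- function(img, geom = NULL, dark = NULL, flat = NULL,
                              solid_angle = FALSE, polarization_factor = NULL,
                              mask = NULL, dummy = NULL, delta_dummy = 0) {
  stopifnot(is.matrix(img))
  m <- matrix(FALSE, nrow(img), ncol(img))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(img)))
    m <- m | mask
  }
  if (!is.null(geom)) m <- m | geom$detector$mask
  if (!is.null(dummy)) m <- m | (abs(img - dummy) <= delta_dummy)
  sig <- img
  if (!is.null(dark)) {
    stopifnot(identical(dim(dark), dim(img)))
    sig <- sig - dark
  }
  if (!is.null(flat)) {
    stopifnot(identical(dim(flat), dim(img)))
    if (any(flat[!m] == 0)) stop("flat field contains zeros on unmasked pixels")
    sig <- sig / flat
  }
  if (solid_angle || !is.null(polarization_factor)) {
    if (is.null(geom)) stop("solid angle / polarization corrections need a geometry")
    ang <- pixel_angles(geom, at = "centers")
    if (solid_angle)
      sig <- sig / solid_angle_map(geom)
    if (!is.null(polarization_factor)) {
      f <- polarization_factor
      P <- 0.5 * (1 + cos(ang$tth)^2 - f * cos(2 * ang$chi) * sin(ang$tth)^2)
      sig <- sig / P
    }
  }
  list(signal = sig, mask = m)
}

#' Relative solid angle map
#'
#' `Omega = cos^3(alpha)` with alpha the angle between the pixel direction
#' (from the sample) and the detector normal; normalised to 1 at the PONI.
#' @param geom an [geometry()].
#' @return numeric matrix `(Ny, Nx)`.
#' @export
solid_angle_map <- function(geom) {
  pos <- pixel_centers(geom$detector)
  m <- matrix(pos, ncol = 3)
  lab <- lab_coordinates(geom, m)
  nrm <- rotation_matrix(geom$rot1, geom$rot2, geom$rot3) %*% c(0, 0, 1)
  ca <- abs(lab %*% nrm) / sqrt(rowSums(lab^2))
  matrix(ca^3, nrow = geom$detector$shape[1])
}

# --------------------------------------------------------------- bin grids

#' Bin grid for azimuthal integration
#'
#' Radial edges are `npt_rad + 1` equally spaced values over
#' `radial_range`; for 2-D integration the azimuthal edges cover
#' `(-pi, pi]`.  Bins are half-open `[lo, hi)` except the last (closed).
#'
#' @param npt_rad number of radial bins.
#' @param radial_range `c(lo, hi)` in the chosen unit.
#' @param unit radial unit tag.
#' @param npt_azim number of azimuthal bins (1 = pure 1-D integration).
#' @return an object of class `"az_grid"`.
#' @export
bin_grid <- function(npt_rad, radial_range, unit = "2th_rad", npt_azim = 1L) {
  stopifnot(npt_rad >= 1, npt_azim >= 1,
            length(radial_range) == 2, radial_range[2] > radial_range[1])
  unit <- match.arg(unit, .az_units)
  structure(list(
    radial_edges = seq(radial_range[1], radial_range[2], length.out = npt_rad + 1),
    azim_edges = seq(-pi, pi, length.out = npt_azim + 1),
    npt_rad = as.integer(npt_rad), npt_azim = as.integer(npt_azim),
    unit = unit), class = "az_grid")
}

grid_radial_centers <- function(grid)
  (grid$radial_edges[-1] + grid$radial_edges[-length(grid$radial_edges)]) / 2
grid_azim_centers <- function(grid)
  (grid$azim_edges[-1] + grid$azim_edges[-length(grid$azim_edges)]) / 2

# per-pixel coordinates (centers + corners) in the requested unit
.pixel_unit_coords <- function(geom, unit, need_corners = TRUE) {
  need_q <- unit %in% c("q_nm^-1", "q_A^-1")
  ctr <- pixel_angles(geom, at = "centers", need_q = need_q)
  out <- list(center_u = as.vector(unit_coordinate(ctr, unit)),
              center_a = as.vector(ctr$chi))
  if (need_corners) {
    cor <- pixel_angles(geom, at = "corners", need_q = need_q)
    npix <- prod(geom$detector$shape)
    out$corner_u <- matrix(unit_coordinate(cor, unit), npix, 4)
    out$corner_a <- matrix(cor$chi, npix, 4)
  }
  out
}

.default_range <- function(coords, scheme, mask) {
  keep <- !as.vector(mask)
  if (scheme == "nosplit") {
    range(coords$center_u[keep])
  } else {
    range(coords$corner_u[keep, ])
  }
}

# ---------------------------------------------------------------- fractions

#' Bounding-box bin fractions of one pixel
#'
#' The pixel is abstracted by the rectangular box `[min, max]` of its corner
#' radial coordinates times `[min, max]` of its corner azimuths; the fraction
#' assigned to a bin is the separable product of the 1-D overlap ratios.
#' Degenerate (zero-width) boxes collapse to no-split points.
#'
#' @param corner_u,corner_a numeric length-4: radial / azimuthal coordinates
#'   of the pixel corners.
#' @param grid an [bin_grid()].
#' @return data.frame `bin_rad`, `bin_azim`, `frac` (1-based bin indices).
#' @export
bbox_fractions <- function(corner_u, corner_a, grid) {
  .quad_fractions(corner_u, corner_a, grid, scheme = 1L)
}

#' Full polygon-clipping bin fractions of one pixel
#'
#' Assumes only that pixel edges are straight lines in `(radial, azimuth)`
#' space: the fraction for a bin is `area(quad intersect bin) / area(quad)`,
#' computed by Sutherland-Hodgman clipping against the bin rectangle.
#'
#' @inheritParams bbox_fractions
#' @export
polygon_fractions <- function(corner_u, corner_a, grid) {
  if (.self_intersecting(corner_u, corner_a))
    stop("pixel quadrilateral is self-intersecting")
  .quad_fractions(corner_u, corner_a, grid, scheme = 2L)
}

.quad_fractions <- function(corner_u, corner_a, grid, scheme) {
  stopifnot(inherits(grid, "az_grid"), length(corner_u) == 4,
            length(corner_a) == 4)
  use_azim <- grid$npt_azim > 1
  res <- cpp_quad_fractions(as.numeric(corner_u), as.numeric(corner_a),
                            grid$radial_edges, grid$azim_edges,
                            scheme, use_azim)
  na <- if (use_azim) grid$npt_azim else 1L
  b0 <- res$bin - 1L
  data.frame(bin_rad = b0 %/% na + 1L, bin_azim = b0 %% na + 1L,
             frac = res$coef)
}

.self_intersecting <- function(u, a) {
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  p <- lapply(1:4, function(k) c(u[k], a[k]))
  seg_int(p[[1]], p[[2]], p[[3]], p[[4]]) || seg_int(p[[2]], p[[3]], p[[4]], p[[1]])
}

# ---------------------------------------------------------------- rebinner

#' Precompute a sparse pixel-to-bin rebinner
#'
#' Builds the pixel -> bin coefficient matrix for one geometry, splitting
#' scheme and bin grid, stored in compressed sparse row (CSR) layout.
#' Applying it is a sparse-matrix-times-vector product, the "gather" dual of
#' direct histogramming.  Coefficients of every unmasked pixel fully inside
#' the radial range sum to one; masked pixels have no entries.
#'
#' @param geom an [geometry()].
#' @param grid an [bin_grid()].
#' @param scheme `"nosplit"`, `"bbox"` or `"fullsplit"`.
#' @param mask optional logical matrix combined with the detector mask.
#' @return an object of class `"az_rebinner"`: fields `matrix` (dgCMatrix,
#'   npix x nbins), `csr` (list `row_ptr`, `col_idx`, `coef`; 0-based,
#'   rows = pixels), `grid`, `scheme`, `shape`, `fingerprint`.
#' @export
build_rebinner <- function(geom, grid, scheme = c("bbox", "nosplit", "fullsplit"),
                           mask = NULL) {
  stopifnot(inherits(geom, "az_geometry"), inherits(grid, "az_grid"))
  scheme <- match.arg(scheme)
  det <- geom$detector
  m <- det$mask
  if (!is.null(mask)) m <- m | mask
  if (all(m)) stop("all pixels are masked")
  coords <- .pixel_unit_coords(geom, grid$unit, need_corners = scheme != "nosplit")
  use_azim <- grid$npt_azim > 1
  scheme_id <- match(scheme, c("nosplit", "bbox", "fullsplit")) - 1L
  if (scheme == "nosplit") {
    npix <- prod(det$shape)
    trip <- cpp_rebin_triplets(matrix(0, 0, 4), matrix(0, 0, 4),
                               coords$center_u, coords$center_a,
                               as.vector(m), grid$radial_edges, grid$azim_edges,
                               scheme_id, use_azim)
  } else {
    trip <- cpp_rebin_triplets(coords$corner_u, coords$corner_a,
                               coords$center_u, coords$center_a,
                               as.vector(m), grid$radial_edges, grid$azim_edges,
                               scheme_id, use_azim)
  }
  npix <- prod(det$shape)
  nbins <- grid$npt_rad * (if (use_azim) grid$npt_azim else 1L)
  A <- Matrix::sparseMatrix(i = trip$pix, j = trip$bin, x = trip$coef,
                            dims = c(npix, nbins))
  R <- as(A, "RsparseMatrix")
  structure(list(matrix = A,
                 csr = list(row_ptr = R@p, col_idx = R@j, coef = R@x),
                 grid = grid, scheme = scheme, shape = det$shape,
                 mask = m,
                 fingerprint = list(dist = geom$dist, poni1 = geom$poni1,
                                    poni2 = geom$poni2, rot1 = geom$rot1,
                                    rot2 = geom$rot2, rot3 = geom$rot3,
                                    wavelength = geom$wavelength,
                                    shape = det$shape, pixel1 = det$pixel1,
                                    pixel2 = det$pixel2, scheme = scheme,
                                    unit = grid$unit,
                                    npt = c(grid$npt_rad, grid$npt_azim))),
            class = "az_rebinner")
}

#' @export
print.az_rebinner <- function(x, ...) {
  cat(sprintf("<az_rebinner %s, %d x %d px -> %d x %d bins (%s), %d coefficients>\n",
              x$scheme, x$shape[1], x$shape[2], x$grid$npt_rad, x$grid$npt_azim,
              x$grid$unit, length(x$csr$coef)))
  invisible(x)
}

# cheap nosplit triplets don't need the empty corner matrices special-cased in
# C++; they are passed as 0-row matrices above.

# weighted-mean + error-model reduction shared by the direct and CSR paths
.reduce_sums <- function(sums, error_model) {
  with(sums, {
    intensity <- ifelse(sum_c > 0, sum_cs / sum_c, NaN)
    sigma <- NULL
    if (error_model %in% c("poisson", "variance")) {
      sigma <- ifelse(sum_c > 0, sqrt(sum_c2v) / sum_c, NaN)
    } else if (error_model == "azimuthal") {
      mean_b <- sum_cs / sum_c
      varw <- pmax(sum_cs2 / sum_c - mean_b^2, 0)
      neff <- ifelse(sum_c2 > 0, sum_c^2 / sum_c2, 0)
      sigma <- ifelse(sum_c > 0 & neff > 0, sqrt(varw / neff), NaN)
    }
    list(intensity = intensity, sigma = sigma, weight = sum_c, count = count)
  })
}

.csr_sums <- function(reb, signal, variance) {
  A <- reb$matrix
  A2 <- A; A2@x <- A@x^2
  s <- as.vector(signal)
  ones <- rep(1, nrow(A))
  list(sum_c = as.vector(Matrix::crossprod(A, ones)),
       sum_c2 = as.vector(Matrix::crossprod(A2, ones)),
       sum_cs = as.vector(Matrix::crossprod(A, s)),
       sum_cs2 = as.vector(Matrix::crossprod(A, s^2)),
       sum_c2v = as.vector(Matrix::crossprod(A2, as.vector(variance))),
       count = diff(A@p))  # nnz per column = contributing pixels per bin
}

#' Propagate per-pixel variance to per-bin sigma
#'
#' Error models: `"poisson"` takes the per-pixel variance equal to the raw
#' signal (clipped at zero, with a warning on negatives); `"variance"` uses a
#' caller-supplied per-pixel variance array; both propagate as
#' `sigma_b^2 = sum(c^2 var) / (sum c)^2`.  `"azimuthal"` postulates
#' isotropy and uses the weighted sample variance of the contributing pixel
#' signals divided by the effective count `(sum c)^2 / sum(c^2)`.
#' Note: pixel splitting introduces serial correlation between neighbouring
#' bins, so split-scheme sigmas are slight overestimates.
#'
#' @param signal corrected signal matrix/vector.
#' @param rebinner an [build_rebinner()] result.
#' @param model `"poisson"`, `"azimuthal"` or `"variance"`.
#' @param raw raw image (Poisson model) or per-pixel variance (`"variance"`).
#' @return numeric vector of per-bin sigma.
#' @export
propagate_errors <- function(signal, rebinner, model = c("poisson", "azimuthal",
                                                         "variance"),
                             raw = NULL) {
  model <- match.arg(model)
  v <- .error_variance(model, raw, signal)
  sums <- .csr_sums(rebinner, signal, v)
  .reduce_sums(sums, model)$sigma
}

.error_variance <- function(model, raw, signal) {
  if (model == "poisson") {
    if (is.null(raw)) raw <- signal
    if (any(raw < 0)) {
      warning("negative raw values clipped to 0 for the Poisson variance model")
      raw <- pmax(raw, 0)
    }
    as.vector(raw)
  } else if (model == "variance") {
    if (is.null(raw)) stop("the variance error model needs a per-pixel variance array")
    as.vector(raw)
  } else {
    rep(0, length(signal))
  }
}

# ---------------------------------------------------------------- integrate

.integrate_core <- function(img, geom, npt_rad, npt_azim, unit, scheme, method,
                            error_model, variance, dark, flat, solid_angle,
                            polarization_factor, mask, dummy, delta_dummy,
                            radial_range, rebinner) {
  unit <- match.arg(unit, .az_units)
  scheme <- match.arg(scheme, c("bbox", "nosplit", "fullsplit"))
  method <- match.arg(method, c("csr", "direct"))
  error_model <- match.arg(error_model, c("none", "poisson", "azimuthal", "variance"))
  corr <- apply_corrections(img, geom, dark = dark, flat = flat,
                            solid_angle = solid_angle,
                            polarization_factor = polarization_factor,
                            mask = mask, dummy = dummy, delta_dummy = delta_dummy)
  if (all(corr$mask)) stop("all pixels are masked")
  v <- if (error_model == "none") rep(0, length(img))
       else .error_variance(error_model, if (error_model == "poisson") img else variance,
                            corr$signal)
  if (!is.null(rebinner)) {
    grid <- rebinner$grid
    reb <- rebinner
  } else {
    coords <- .pixel_unit_coords(geom, unit, need_corners = scheme != "nosplit")
    rng <- if (is.null(radial_range)) .default_range(coords, scheme, corr$mask)
           else radial_range
    grid <- bin_grid(npt_rad, rng, unit = unit, npt_azim = npt_azim)
    reb <- NULL
  }
  use_azim <- grid$npt_azim > 1
  if (method == "csr") {
    if (is.null(reb)) reb <- build_rebinner(geom, grid, scheme, mask = corr$mask)
    sums <- .csr_sums(reb, corr$signal, v)
  } else {
    coords <- .pixel_unit_coords(geom, grid$unit, need_corners = scheme != "nosplit")
    scheme_id <- match(scheme, c("nosplit", "bbox", "fullsplit")) - 1L
    cu <- if (scheme == "nosplit") matrix(0, 0, 4) else coords$corner_u
    ca <- if (scheme == "nosplit") matrix(0, 0, 4) else coords$corner_a
    sums <- cpp_rebin_direct(cu, ca, coords$center_u, coords$center_a,
                             as.vector(corr$mask), grid$radial_edges,
                             grid$azim_edges, scheme_id, use_azim,
                             as.vector(corr$signal), v)
  }
  red <- .reduce_sums(sums, error_model)
  res <- list(radial = grid_radial_centers(grid),
              unit = grid$unit, scheme = scheme, method = method,
              error_model = error_model, grid = grid)
  if (use_azim) {
    na <- grid$npt_azim
    res$azimuth <- grid_azim_centers(grid)
    res$intensity <- matrix(red$intensity, grid$npt_rad, na, byrow = TRUE)
    res$sigma <- if (!is.null(red$sigma)) matrix(red$sigma, grid$npt_rad, na, byrow = TRUE)
    res$weight <- matrix(red$weight, grid$npt_rad, na, byrow = TRUE)
    res$count <- matrix(red$count, grid$npt_rad, na, byrow = TRUE)
  } else {
    res$intensity <- red$intensity
    res$sigma <- red$sigma
    res$weight <- red$weight
    res$count <- red$count
  }
  class(res) <- "az_result"
  res
}

#' One-dimensional azimuthal integration
#'
#' Reduces a 2-D detector image to a 1-D scattering pattern: per radial bin,
#' the coefficient-weighted mean of the corrected pixel signals,
#' `I_b = sum_p c_pb s_p / sum_p c_pb`.  The `direct` method scatters pixel
#' by pixel like a histogram; the `csr` method applies the precomputed
#' sparse rebinner (gather) - both produce identical results.  Empty bins
#' report `NaN`.
#'
#' @param img numeric matrix (raw image).
#' @param geom an [geometry()].
#' @param npt number of radial bins.
#' @param unit output space: `"2th_deg"`, `"2th_rad"`, `"q_nm^-1"`,
#'   `"q_A^-1"`, `"r_m"`, `"r_mm"`.
#' @param scheme pixel splitting: `"bbox"` (default), `"nosplit"`,
#'   `"fullsplit"`.
#' @param method `"csr"` (sparse rebinner) or `"direct"` (histogram).
#' @param error_model `"none"`, `"poisson"`, `"azimuthal"` or `"variance"`.
#' @param variance per-pixel variance matrix (for `error_model =
#'   "variance"`).
#' @param dark,flat,solid_angle,polarization_factor,mask,dummy,delta_dummy
#'   corrections, see [apply_corrections()].
#' @param radial_range optional `c(lo, hi)` in `unit`; default spans the
#'   (corner-based for splitting schemes) coordinates of unmasked pixels.
#' @param rebinner optional precomputed [build_rebinner()] to reuse.
#' @return an `"az_result"`: `radial`, `intensity`, `sigma` (or NULL),
#'   `weight`, `count`.
#' @examples
#' det <- detector(c(64, 64), 2e-4)
#' geom <- geometry(det, dist = 0.05, poni1 = 64e-4, poni2 = 64e-4)
#' res <- integrate1d(matrix(1, 64, 64), geom, npt = 32)
#' stopifnot(all(abs(res$intensity[res$count > 0] - 1) < 1e-9))
#' @export
integrate1d <- function(img, geom, npt = 1000, unit = "2th_deg",
                        scheme = c("bbox", "nosplit", "fullsplit"),
                        method = c("csr", "direct"),
                        error_model = c("none", "poisson", "azimuthal", "variance"),
                        variance = NULL, dark = NULL, flat = NULL,
                        solid_angle = FALSE, polarization_factor = NULL,
                        mask = NULL, dummy = NULL, delta_dummy = 0,
                        radial_range = NULL, rebinner = NULL) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  error_model <- match.arg(error_model)
  .integrate_core(img, geom, npt, 1L, unit, scheme, method, error_model,
                  variance, dark, flat, solid_angle, polarization_factor,
                  mask, dummy, delta_dummy, radial_range, rebinner)
}

#' Two-dimensional azimuthal integration
#'
#' Same reduction as [integrate1d()] on the outer product of a radial and an
#' azimuthal grid (`chi` over `(-pi, pi]`): a "cake" image `(npt_rad,
#' npt_azim)`.  Marginalising the result over `chi` with the per-bin weights
#' reproduces the 1-D integration.
#'
#' @inheritParams integrate1d
#' @param npt_rad,npt_azim number of radial / azimuthal bins.
#' @return an `"az_result"` with matrix fields `intensity`, `weight`,
#'   `count` of shape `(npt_rad, npt_azim)` plus `radial` and `azimuth`
#'   center vectors.
#' @export
integrate2d <- function(img, geom, npt_rad = 1000, npt_azim = 360,
                        unit = "2th_deg",
                        scheme = c("bbox", "nosplit", "fullsplit"),
                        method = c("csr", "direct"),
                        error_model = c("none", "poisson", "azimuthal", "variance"),
                        variance = NULL, dark = NULL, flat = NULL,
                        solid_angle = FALSE, polarization_factor = NULL,
                        mask = NULL, dummy = NULL, delta_dummy = 0,
                        radial_range = NULL, rebinner = NULL) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  error_model <- match.arg(error_model)
  stopifnot(npt_azim >= 2)
  .integrate_core(img, geom, npt_rad, npt_azim, unit, scheme, method,
                  error_model, variance, dark, flat, solid_angle,
                  polarization_factor, mask, dummy, delta_dummy,
                  radial_range, rebinner)
}

#' @export
print.az_result <- function(x, ...) {
  if (is.matrix(x$intensity))
    cat(sprintf("<az_result 2-D: %d x %d bins (%s), scheme=%s, method=%s>\n",
                nrow(x$intensity), ncol(x$intensity), x$unit, x$scheme, x$method))
  else
    cat(sprintf("<az_result 1-D: %d bins (%s), scheme=%s, method=%s, %d empty>\n",
                length(x$intensity), x$unit, x$scheme, x$method,
                sum(!is.finite(x$intensity))))
  invisible(x)
}

#' Write a 1-D integration result as ASCII
#'
#' Three columns (radial, intensity, sigma) with `#` header metadata carrying
#' the unit, scheme, method, error model and geometry fingerprint.  With a
#' split scheme the sigma column slightly overestimates the true error
#' (bin-to-bin correlation induced by pixel splitting).
#'
#' @param res an `"az_result"` from [integrate1d()].
#' @param path output path.
#' @param extra named character vector of additional header lines.
#' @export
write_pattern <- function(res, path, extra = NULL) {
  stopifnot(inherits(res, "az_result"), !is.matrix(res$intensity))
  hdr <- c(sprintf("# unit: %s", res$unit),
           sprintf("# scheme: %s", res$scheme),
           sprintf("# method: %s", res$method),
           sprintf("# error_model: %s", res$error_model),
           "# note: pixel splitting correlates neighbouring bins; sigma is an upper bound",
           sprintf("# columns: radial intensity%s",
                   if (is.null(res$sigma)) "" else " sigma"))
  if (!is.null(extra)) hdr <- c(hdr, sprintf("# %s: %s", names(extra), extra))
  tab <- if (is.null(res$sigma)) cbind(res$radial, res$intensity)
         else cbind(res$radial, res$intensity, res$sigma)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(tab, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 1-D pattern written by [write_pattern()]
#' @param path file path.
#' @return data.frame with columns `radial`, `intensity` and possibly `sigma`.
#' @export
read_pattern <- function(path) {
  tab <- read.table(path, comment.char = "#")
  names(tab) <- c("radial", "intensity", "sigma")[seq_len(ncol(tab))]
  tab
}
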