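#' Gaussian blur of an image
#'
#' Separable real-space convolution (no FFT), kernel truncated at +/- 4
#' sigma, symmetric-reflection boundary handling.
#' @param img numeric matrix.
#' @param sigma blur width in pixels.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  cpp_gaussian_blur(img, sigma)
}

# 2-D quadratic-fit displacement on a 3x3 patch; fallback to the (nonnegative)
# intensity-weighted centre of mass when the Newton step leaves the patch.
subpixel_delta2 <- function(patch) {
  g <- c((patch[3, 2] - patch[1, 2]) / 2, (patch[2, 3] - patch[2, 1]) / 2)
  hyy <- patch[1, 2] - 2 * patch[2, 2] + patch[3, 2]
  hxx <- patch[2, 1] - 2 * patch[2, 2] + patch[2, 3]
  hxy <- (patch[3, 3] - patch[3, 1] - patch[1, 3] + patch[1, 1]) / 4
  H <- matrix(c(hyy, hxy, hxy, hxx), 2, 2)
  d <- tryCatch(solve(H, -g), error = function(e) c(Inf, Inf))
  fallback <- any(!is.finite(d)) || any(abs(d) > 1)
  if (fallback) {
    w <- pmax(patch, 0)
    sw <- sum(w)
    off <- c(-1, 0, 1)
    d <- if (sw > 0) c(sum(w * off) / sw, sum(t(w) * off) / sw) else c(0, 0)
  }
  list(delta = d, fallback = fallback)
}

# 3-D analogue on a 3x3x3 patch over (y, x, scale)
subpixel_delta3 <- function(patch) {
  g <- c((patch[3, 2, 2] - patch[1, 2, 2]) / 2,
         (patch[2, 3, 2] - patch[2, 1, 2]) / 2,
         (patch[2, 2, 3] - patch[2, 2, 1]) / 2)
  h11 <- patch[1, 2, 2] - 2 * patch[2, 2, 2] + patch[3, 2, 2]
  h22 <- patch[2, 1, 2] - 2 * patch[2, 2, 2] + patch[2, 3, 2]
  h33 <- patch[2, 2, 1] - 2 * patch[2, 2, 2] + patch[2, 2, 3]
  h12 <- (patch[3, 3, 2] - patch[3, 1, 2] - patch[1, 3, 2] + patch[1, 1, 2]) / 4
  h13 <- (patch[3, 2, 3] - patch[3, 2, 1] - patch[1, 2, 3] + patch[1, 2, 1]) / 4
  h23 <- (patch[2, 3, 3] - patch[2, 3, 1] - patch[2, 1, 3] + patch[2, 1, 1]) / 4
  H <- matrix(c(h11, h12, h13, h12, h22, h23, h13, h23, h33), 3, 3)
  d <- tryCatch(solve(H, -g), error = function(e) rep(Inf, 3))
  fallback <- any(!is.finite(d)) || any(abs(d) > 1)
  if (fallback) {
    w <- pmax(patch, 0)
    sw <- sum(w)
    off <- c(-1, 0, 1)
    if (sw > 0) {
      d <- c(sum(apply(w, 1, sum) * off),
             sum(apply(w, 2, sum) * off),
             sum(apply(w, 3, sum) * off)) / sw
    } else d <- c(0, 0, 0)
  }
  list(delta = d, fallback = fallback)
}

#' Subpixel refinement of a local maximum
#'
#' Second-order Taylor expansion of the intensity around the maximum pixel:
#' with gradient `g` and Hessian `H` estimated by central differences on the
#' 3x3 neighbourhood, the displacement is `delta = -H^-1 g`.  If `H` is
#' singular or any component of `delta` exceeds one pixel (a sign the
#' quadratic model broke down on noisy data), the intensity-weighted centre
#' of mass of the 3x3 patch is used instead (less precise, more robust).
#'
#' @param img numeric matrix.
#' @param pos integer `(y, x)` of the maximum, strictly interior
#'   (at least one pixel from every border).
#' @return numeric `(y, x)` subpixel position; attribute `fallback` says
#'   whether the centre-of-mass fallback was used.
#' @examples
#' yy <- outer(1:9, rep(1, 9)); xx <- t(yy)
#' img <- 10 - (yy - 5.3)^2 - (xx - 4.7)^2
#' refine_subpixel(img, c(5, 5))  # recovers (5.3, 4.7) exactly
#' @export
refine_subpixel <- function(img, pos) {
  stopifnot(is.matrix(img), length(pos) == 2)
  y <- as.integer(pos[1]); x <- as.integer(pos[2])
  if (y < 2 || x < 2 || y > nrow(img) - 1 || x > ncol(img) - 1)
    stop("position must be at least one pixel away from every border")
  res <- subpixel_delta2(img[(y - 1):(y + 1), (x - 1):(x + 1)])
  structure(c(y, x) + res$delta, fallback = res$fallback)
}

#' Massif extraction
#'
#' Separates high-count regions (rings) from background by subtracting a
#' Gaussian-blurred copy of the image from the image itself: positive
#' connected components of the difference are "massifs", and peaks sampled
#' within one massif belong to the same ring.  All strict 3x3 local maxima
#' inside each massif are returned, refined to subpixel accuracy.
#'
#' The blur width must exceed the typical peak-to-peak distance along a ring
#' and stay below the ring-to-ring distance; the default heuristic is
#' `max(3, min(dim(img)) / 100)` pixels and can be overridden (the command
#' line exposes it as `--gaussian`).
#'
#' @param img numeric matrix.
#' @param sigma blur width in pixels, `NULL` for the heuristic default.
#' @param mask optional logical matrix, `TRUE` = invalid.
#' @return list with `sigma`, `labels` (integer matrix, 0 = background) and
#'   `peaks` (data.frame `y`, `x`, `region`, `intensity`, `fallback`).
#' @export
massif_extract <- function(img, sigma = NULL, mask = NULL) {
  stopifnot(is.matrix(img))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(img), ncol(img))
  if (all(mask)) stop("all pixels are masked")
  if (is.null(sigma)) sigma <- max(3, min(dim(img)) / 100)
  if (sigma <= 0) stop("sigma must be positive")
  diff <- img - cpp_gaussian_blur(img, sigma)
  # strictly-positive difference, with a relative floor so kernel rounding
  # (~1e-16) on flat images cannot fabricate regions
  pos <- diff > 1e-8 * max(abs(img), 1e-300) & !mask
  labels <- cpp_label_components(pos)
  mx <- cpp_local_max2(img, pos)
  peaks <- data.frame(y = numeric(0), x = numeric(0), region = integer(0),
                      intensity = numeric(0), fallback = logical(0))
  if (nrow(mx) > 0) {
    ref <- t(apply(mx, 1, function(p) {
      r <- refine_subpixel(img, p)
      c(r, attr(r, "fallback"))
    }))
    peaks <- data.frame(y = ref[, 1], x = ref[, 2],
                        region = labels[mx],
                        intensity = img[mx],
                        fallback = as.logical(ref[, 3]))
  }
  list(sigma = sigma, labels = labels, peaks = peaks)
}

# ------------------------------------------------------------- scale space

# Per-octave relative blur levels (geometric, ratio sqrt(2)); the level at
# relative sigma 2 seeds the next octave after 2x2-mean downsampling.
.ss_levels <- 2^(seq(0, 2, by = 0.5))          # 1, sqrt2, 2, 2*sqrt2, 4
.ss_dog_sigma <- sqrt(.ss_levels[-5] * .ss_levels[-1])  # assigned DoG scales

#' Difference-of-Gaussians scale space
#'
#' Blurs the image along the geometric sigma series `1, sqrt(2), 2,
#' 2*sqrt(2), 4` (in units of the current pyramid level), forms DoG images
#' (finer minus coarser, so bright blobs are maxima), and builds a pyramid by
#' 2x2-mean binning of the level blurred at sigma = 2 so convolution kernels
#' stay small.
#'
#' @param img numeric matrix.
#' @param n_octaves maximum number of pyramid octaves.
#' @return list of octaves; each has `dogs` (3-D array `(ny, nx, 4)`),
#'   `sigmas` (absolute DoG scales in original pixels) and `factor`
#'   (downsampling factor).
#' @export
scale_space <- function(img, n_octaves = 8) {
  oct <- list()
  base <- img
  f <- 1L
  for (o in seq_len(n_octaves)) {
    if (min(dim(base)) < 16) break
    blurs <- vector("list", 5)
    prev_s <- if (o == 1) 0 else 1   # downsampled seed already carries sigma 1
    cur <- base
    for (k in 1:5) {
      inc <- sqrt(.ss_levels[k]^2 - prev_s^2)
      cur <- cpp_gaussian_blur(cur, inc)
      blurs[[k]] <- cur
      prev_s <- .ss_levels[k]
    }
    dogs <- array(0, c(dim(base), 4))
    for (k in 1:4) dogs[, , k] <- blurs[[k]] - blurs[[k + 1]]
    oct[[o]] <- list(dogs = dogs, sigmas = .ss_dog_sigma * f, factor = f)
    base <- cpp_downsample2(blurs[[3]])   # relative sigma 2 -> 1 after binning
    f <- f * 2L
  }
  oct
}

#' Blob detection in scale space
#'
#' Keypoints are strict 3x3x3 local maxima of the DoG stack (interior in
#' position and scale), refined by the three-dimensional analogue of
#' [refine_subpixel()] over `(y, x, sigma)` with the same
#' fallback-to-centroid rule, then mapped back through the pyramid octaves.
#' The smallest detectable peak width is about 3 pixels (FWHM); narrower
#' peaks never produce an interior scale-space maximum.
#'
#' @param img numeric matrix.
#' @param mask optional logical matrix; masked pixels are replaced by the
#'   image median before blurring and keypoints within 2 px of a masked
#'   pixel are discarded.
#' @param threshold minimum DoG value of a candidate maximum (absolute, same
#'   scale as the image); 0 keeps everything including noise maxima.
#' @return data.frame `y`, `x`, `sigma`, `intensity` (refined DoG response)
#'   in full-resolution pixel coordinates.
#' @export
blob_detect <- function(img, mask = NULL, threshold = 0) {
  stopifnot(is.matrix(img))
  work <- img
  if (!is.null(mask) && any(mask)) {
    work[mask] <- median(img[!mask])
    near_mask <- cpp_gaussian_blur(mask + 0, 1.5) > 1e-4
  } else near_mask <- NULL
  oct <- scale_space(work)
  out <- list()
  log_step <- log(sqrt(2))
  # same rounding floor as the massif: a flat image must yield no keypoints
  threshold <- max(threshold, 1e-12 * max(abs(work), 1e-300))
  for (o in seq_along(oct)) {
    dg <- oct[[o]]$dogs
    f <- oct[[o]]$factor
    valid <- matrix(TRUE, dim(dg)[1], dim(dg)[2])
    mx <- cpp_local_max3(dg, valid, threshold)
    if (nrow(mx) == 0) next
    res <- matrix(0, nrow(mx), 4)
    for (t in seq_len(nrow(mx))) {
      i <- mx[t, 1]; j <- mx[t, 2]; k <- mx[t, 3]
      r3 <- subpixel_delta3(dg[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])
      yo <- i + r3$delta[1]; xo <- j + r3$delta[2]
      res[t, 1] <- (yo - 0.5) * f + 0.5
      res[t, 2] <- (xo - 0.5) * f + 0.5
      res[t, 3] <- oct[[o]]$sigmas[k] * exp(r3$delta[3] * log_step)
      res[t, 4] <- dg[i, j, k]
    }
    out[[o]] <- res
  }
  if (length(out) == 0)
    return(data.frame(y = numeric(0), x = numeric(0), sigma = numeric(0),
                      intensity = numeric(0)))
  res <- do.call(rbind, out)
  kp <- data.frame(y = res[, 1], x = res[, 2], sigma = res[, 3],
                   intensity = res[, 4])
  kp <- kp[kp$y >= 1 & kp$y <= nrow(img) & kp$x >= 1 & kp$x <= ncol(img), ]
  if (!is.null(near_mask)) {
    iy <- pmin(pmax(round(kp$y), 1), nrow(img))
    ix <- pmin(pmax(round(kp$x), 1), ncol(img))
    kp <- kp[!near_mask[cbind(iy, ix)], ]
  }
  rownames(kp) <- NULL
  kp
}

# ----------------------------------------------------------- control points

#' Control point sets
#'
#' Labelled groups of subpixel peak positions, each group assigned to one
#' calibrant ring (1-based index into `ring_angles`).  `points` is a
#' data.frame with columns `ring`, `y`, `x`.
#'
#' @param points data.frame with columns `ring`, `y`, `x`.
#' @param shape source image shape `(Ny, Nx)`.
#' @return an object of class `"az_control_points"`.
#' @export
control_points <- function(points, shape) {
  stopifnot(is.data.frame(points), all(c("ring", "y", "x") %in% names(points)))
  if (nrow(points) > 0) {
    if (any(points$ring < 1))
      stop("ring indices must be >= 1")
    if (any(points$y < 0.5 | points$y > shape[1] + 0.5 |
            points$x < 0.5 | points$x > shape[2] + 0.5))
      stop("control points must lie inside the image bounds")
  }
  structure(list(points = points[order(points$ring), , drop = FALSE],
                 shape = as.integer(shape)),
            class = "az_control_points")
}

#' @export
print.az_control_points <- function(x, ...) {
  cat(sprintf("<az_control_points: %d points on %d ring(s), image %d x %d>\n",
              nrow(x$points), length(unique(x$points$ring)),
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' @rdname control_points
#' @param cps an `az_control_points` object.
#' @param path file path ("ring y x" per line, `#` comments).
#' @export
write_control_points <- function(cps, path) {
  stopifnot(inherits(cps, "az_control_points"))
  hdr <- c("# control points: ring_index y x (1-based, pixel-center units)",
           sprintf("# image_shape: %d %d", cps$shape[1], cps$shape[2]))
  body <- sprintf("%d %.6f %.6f", cps$points$ring, cps$points$y, cps$points$x)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname control_points
#' @export
read_control_points <- function(path) {
  if (!file.exists(path)) stop("control point file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  shape_line <- grep("^# image_shape:", lines, value = TRUE)
  shape <- if (length(shape_line))
    as.integer(strsplit(trimws(sub("^# image_shape:", "", shape_line[1])), "\\s+")[[1]])
  else c(NA_integer_, NA_integer_)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0)
    return(control_points(data.frame(ring = integer(), y = numeric(),
                                     x = numeric()), shape))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  control_points(data.frame(ring = as.integer(m[, 1]), y = m[, 2], x = m[, 3]),
                 shape)
}

#' Extract ring-labelled control points
#'
#' Runs [blob_detect()] and assigns each keypoint to the nearest calibrant
#' ring whose aperture differs from the keypoint's scattering angle (under
#' the approximate geometry) by less than `tol_tth`; unassigned keypoints are
#' discarded.  Used in the (re)calibration flow where an approximate geometry
#' restricts the region of interest.
#'
#' @param img numeric matrix.
#' @param geom approximate [geometry()].
#' @param cal [calibrant()] with wavelength (or wavelength on `geom`).
#' @param tol_tth assignment tolerance in radians of 2-theta.
#' @param mask optional logical matrix.
#' @param threshold DoG threshold passed to [blob_detect()]; the default
#'   keeps keypoints whose response exceeds 1e-3 of the image maximum,
#'   suppressing flat-field noise maxima.
#' @return an [control_points()] object.
#' @export
extract_for_rings <- function(img, geom, cal, tol_tth, mask = NULL,
                              threshold = NULL) {
  if (tol_tth <= 0) stop("tol_tth must be positive (no keypoint can be assigned)")
  wl <- if (!is.null(cal$wavelength)) cal$wavelength else geom$wavelength
  rings <- ring_angles(cal, wl)
  if (is.null(threshold)) threshold <- 1e-3 * max(img)
  kp <- blob_detect(img, mask = mask, threshold = threshold)
  if (nrow(kp) == 0) stop("no keypoint was assigned to any ring")
  tth <- point_angles(geom, kp$y, kp$x)$tth
  idx <- vapply(tth, function(t) which.min(abs(rings - t)), 1L)
  dev <- abs(rings[idx] - tth)
  keep <- dev < tol_tth
  if (!any(keep)) stop("no keypoint was assigned to any ring")
  control_points(data.frame(ring = idx[keep], y = kp$y[keep], x = kp$x[keep]),
                 dim(img))
}
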