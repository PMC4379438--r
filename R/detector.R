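#' Area detector model
#'
#' A detector is a field of pixel corner coordinates in the detector frame.
#' The frame has axis 1 along the slow (vertical, row) direction and axis 2
#' along the fast (horizontal, column) direction, origin at the lower-left
#' pixel corner as seen from the sample; all lengths are in metres.  For a
#' regular-grid detector pixel `(i, j)` (1-based) spans
#' `[(i-1), i] * pixel1` x `[(j-1), j] * pixel2` with the third coordinate 0.
#' Irregular layouts (module gaps, tiled modules) are described by an explicit
#' corner array of shape `(Ny, Nx, 4, 3)`.
#'
#' @param shape integer length-2, `(Ny, Nx)` pixel counts.
#' @param pixel1,pixel2 pixel extent (metres) along the slow / fast axis.
#' @param mask logical `Ny x Nx` matrix, `TRUE` = invalid pixel; default none.
#' @param corners optional numeric array `(Ny, Nx, 4, 3)` of pixel corner
#'   positions (metres).  Corners of each pixel must be ordered
#'   counter-clockwise starting at the `(i, j)` corner and form a simple
#'   quadrilateral.
#' @param binning integer length-2 bookkeeping of applied binning factors.
#' @return an object of class `"az_detector"`.
#' @examples
#' det <- detector(c(64, 64), 1e-4, 1e-4)
#' dim(pixel_corners(det))
#' @export
detector <- function(shape, pixel1, pixel2 = pixel1, mask = NULL,
                     corners = NULL, binning = c(1L, 1L)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 1),
            is.numeric(pixel1), pixel1 > 0, is.numeric(pixel2), pixel2 > 0)
  if (is.null(mask)) {
    mask <- matrix(FALSE, shape[1], shape[2])
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    if (!identical(dim(mask), shape))
      stop("mask shape (", paste(dim(mask), collapse = "x"),
           ") does not match detector shape (", paste(shape, collapse = "x"), ")")
  }
  if (!is.null(corners)) {
    if (length(dim(corners)) != 4 ||
        !identical(dim(corners)[1:2], shape) ||
        dim(corners)[3] != 4 || dim(corners)[4] != 3)
      stop("corners must be a (Ny, Nx, 4, 3) array matching the detector shape")
    storage.mode(corners) <- "double"
  }
  structure(list(shape = shape, pixel1 = pixel1, pixel2 = pixel2,
                 mask = mask, corners = corners,
                 binning = as.integer(binning)),
            class = "az_detector")
}

#' @export
print.az_detector <- function(x, ...) {
  cat(sprintf("<az_detector %d x %d, pixel %.3g x %.3g m, %s corners, %d masked>\n",
              x$shape[1], x$shape[2], x$pixel1, x$pixel2,
              if (is.null(x$corners)) "regular" else "explicit", sum(x$mask)))
  invisible(x)
}

#' Pixel corner coordinates
#'
#' Returns the `(Ny, Nx, 4, 3)` array of pixel corner positions in the
#' detector frame (metres).  For regular-grid detectors the corners are
#' implied by the pixel size; explicit corner arrays are returned as stored.
#' Corner order is counter-clockwise starting at the `(i, j)` corner.
#'
#' @param det an [detector()] object.
#' @return numeric array `(Ny, Nx, 4, 3)`.
#' @export
pixel_corners <- function(det) {
  stopifnot(inherits(det, "az_detector"))
  if (!is.null(det$corners)) return(det$corners)
  ny <- det$shape[1]; nx <- det$shape[2]
  p1 <- (seq_len(ny) - 1) * det$pixel1   # lower edge of row i
  p2 <- (seq_len(nx) - 1) * det$pixel2
  out <- array(0, c(ny, nx, 4, 3))
  # CCW in (axis1 up, axis2 right): (i,j), (i,j+1), (i+1,j+1), (i+1,j)
  out[, , 1, 1] <- p1;              out[, , 1, 2] <- rep(p2, each = ny)
  out[, , 2, 1] <- p1;              out[, , 2, 2] <- rep(p2 + det$pixel2, each = ny)
  out[, , 3, 1] <- p1 + det$pixel1; out[, , 3, 2] <- rep(p2 + det$pixel2, each = ny)
  out[, , 4, 1] <- p1 + det$pixel1; out[, , 4, 2] <- rep(p2, each = ny)
  out
}

#' Pixel center coordinates
#'
#' Arithmetic mean of the four pixel corners, shape `(Ny, Nx, 3)` (metres).
#' This is the position used by the no-splitting integration scheme.
#'
#' @inheritParams pixel_corners
#' @return numeric array `(Ny, Nx, 3)`.
#' @export
pixel_centers <- function(det) {
  stopifnot(inherits(det, "az_detector"))
  if (is.null(det$corners)) {
    ny <- det$shape[1]; nx <- det$shape[2]
    out <- array(0, c(ny, nx, 3))
    out[, , 1] <- (seq_len(ny) - 0.5) * det$pixel1
    out[, , 2] <- rep((seq_len(nx) - 0.5) * det$pixel2, each = ny)
    return(out)
  }
  cr <- det$corners
  out <- (cr[, , 1, , drop = FALSE] + cr[, , 2, , drop = FALSE] +
          cr[, , 3, , drop = FALSE] + cr[, , 4, , drop = FALSE]) / 4
  array(out, c(det$shape, 3))
}

#' Bin a detector
#'
#' Merges `b1 x b2` blocks of pixels into larger pixels: the shape is divided,
#' pixel sizes multiplied, a binned pixel is masked iff any constituent is
#' masked, and for explicit corner arrays the binned corner envelope is the
#' outer envelope of the constituents.  The geometry (PONI) does not change
#' under binning because positions are expressed in metres, not pixels.
#'
#' @inheritParams pixel_corners
#' @param b1,b2 integer binning factors; must divide the detector shape.
#' @return a new [detector()].
#' @export
detector_bin <- function(det, b1, b2) {
  stopifnot(inherits(det, "az_detector"))
  b1 <- as.integer(b1); b2 <- as.integer(b2)
  if (b1 < 1 || b2 < 1)
    stop("binning factors must be >= 1")
  if (det$shape[1] %% b1 != 0 || det$shape[2] %% b2 != 0)
    stop("binning factors (", b1, ", ", b2, ") do not divide the detector shape (",
         paste(det$shape, collapse = ", "), ")")
  if (b1 == 1 && b2 == 1) return(det)
  ny <- det$shape[1] %/% b1; nx <- det$shape[2] %/% b2
  gi <- rep(seq_len(ny), each = b1)   # group of each original row
  gj <- rep(seq_len(nx), each = b2)
  mask <- matrix(FALSE, ny, nx)
  anym <- rowsum(t(rowsum(det$mask + 0, gi)), gj)  # nx x ny sums
  mask <- t(anym) > 0
  dimnames(mask) <- NULL
  corners <- NULL
  if (!is.null(det$corners)) {
    corners <- array(0, c(ny, nx, 4, 3))
    cr <- det$corners
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      ii <- ((i - 1) * b1 + 1):(i * b1); jj <- ((j - 1) * b2 + 1):(j * b2)
      sub <- cr[ii, jj, , , drop = FALSE]
      lo1 <- min(sub[, , , 1]); hi1 <- max(sub[, , , 1])
      lo2 <- min(sub[, , , 2]); hi2 <- max(sub[, , , 2])
      z <- mean(sub[, , , 3])
      corners[i, j, , ] <- cbind(c(lo1, lo1, hi1, hi1), c(lo2, hi2, hi2, lo2), z)
    }
  }
  detector(c(ny, nx), det$pixel1 * b1, det$pixel2 * b2, mask = mask,
           corners = corners, binning = det$binning * c(b1, b2))
}

#' Save / load a detector definition
#'
#' Persists shape, pixel sizes, mask and (when present) the explicit corner
#' array.  The file is a single JSON document with datasets named
#' `pixel_corners` (flattened `(Ny, Nx, 4, 3)`, metres), `mask`, and
#' attributes `pixel1`, `pixel2`, `format_version`.  (A NeXus/HDF5 container
#' would carry the same datasets; this build has no HDF5 binding available,
#' so the same layout is stored as text.)
#'
#' @inheritParams pixel_corners
#' @param path file path.
#' @return `detector_save` returns `path` invisibly; `detector_load` returns
#'   an [detector()].
#' @export
detector_save <- function(det, path) {
  stopifnot(inherits(det, "az_detector"))
  obj <- list(format_version = "1",
              shape = det$shape,
              pixel1 = det$pixel1, pixel2 = det$pixel2,
              binning = det$binning,
              mask = as.integer(det$mask))
  if (!is.null(det$corners)) obj$pixel_corners <- as.vector(det$corners)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname detector_save
#' @param with_corners require the `pixel_corners` dataset to be present.
#' @export
detector_load <- function(path, with_corners = FALSE) {
  if (!file.exists(path)) stop("detector file not found: ", path)
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  for (key in c("shape", "pixel1", "pixel2", "mask"))
    if (is.null(obj[[key]]))
      stop("detector file ", path, " lacks dataset '", key, "'")
  shape <- as.integer(obj$shape)
  if (length(obj$mask) != prod(shape))
    stop("dataset 'mask' has wrong length in ", path)
  corners <- NULL
  if (!is.null(obj$pixel_corners)) {
    if (length(obj$pixel_corners) != prod(shape) * 12)
      stop("dataset 'pixel_corners' has wrong rank/length in ", path)
    corners <- array(obj$pixel_corners, c(shape, 4, 3))
  } else if (with_corners) {
    stop("detector file ", path, " lacks dataset 'pixel_corners'")
  }
  detector(shape, obj$pixel1, obj$pixel2,
           mask = matrix(as.logical(obj$mask), shape[1], shape[2]),
           corners = corners,
           binning = if (is.null(obj$binning)) c(1L, 1L) else as.integer(obj$binning))
}

#' Two-module gapped detector fixture
#'
#' An explicit-corner detector made of two modules of `nrow_module` rows each,
#' separated by a gap of `gap` pixel heights (synthetic stand-in for a
#' multi-module pixel detector).  Rows of the second module are displaced by
#' the gap, so the corner array is genuinely irregular.
#'
#' @param shape `(Ny, Nx)`; `Ny` must be even.
#' @param pixel1,pixel2 pixel sizes (metres).
#' @param gap gap between the two modules in units of `pixel1`.
#' @return an [detector()] with explicit corners.
#' @export
detector_gapped <- function(shape = c(64L, 64L), pixel1 = 1e-4, pixel2 = 1e-4,
                            gap = 3) {
  shape <- as.integer(shape)
  stopifnot(shape[1] %% 2 == 0)
  ny <- shape[1]; nx <- shape[2]
  half <- ny %/% 2
  row_lo <- (seq_len(ny) - 1) * pixel1
  shift <- ifelse(seq_len(ny) > half, gap * pixel1, 0)
  row_lo <- row_lo + shift
  col_lo <- (seq_len(nx) - 1) * pixel2
  corners <- array(0, c(ny, nx, 4, 3))
  corners[, , 1, 1] <- row_lo;          corners[, , 1, 2] <- rep(col_lo, each = ny)
  corners[, , 2, 1] <- row_lo;          corners[, , 2, 2] <- rep(col_lo + pixel2, each = ny)
  corners[, , 3, 1] <- row_lo + pixel1; corners[, , 3, 2] <- rep(col_lo + pixel2, each = ny)
  corners[, , 4, 1] <- row_lo + pixel1; corners[, , 4, 2] <- rep(col_lo, each = ny)
  detector(shape, pixel1, pixel2, corners = corners)
}

# quad area per pixel (shoelace over the 4 corners), used by conservation tests
pixel_areas <- function(det) {
  cr <- pixel_corners(det)
  a <- cr[, , , 1]; b <- cr[, , , 2]
  s <- 0
  for (k in 1:4) {
    k2 <- if (k == 4) 1 else k + 1
    s <- s + a[, , k] * b[, , k2] - a[, , k2] * b[, , k]
  }
  abs(s) / 2
}
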