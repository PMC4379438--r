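#' Experiment geometry (PONI parametrisation)
#'
#' The detector is a rigid body whose position relative to the sample is
#' described by six parameters: `dist`, the sample-to-detector distance
#' measured along the detector normal; `poni1`, `poni2`, the coordinates of
#' the PONI (point of normal incidence, the orthogonal projection of the
#' sample onto the detector plane) in the detector frame; and three rotations
#' `rot1`, `rot2`, `rot3` (radians) about the vertical axis, the horizontal
#' axis and the beam axis, applied in that order.  All distances are metres.
#' With all rotations zero the detector is in transmission mode, beam
#' orthogonal to its surface, and the PONI maps to the lab point
#' `(0, 0, dist)`.
#'
#' Conventions frozen here (any self-consistent choice works): right-handed
#' lab frame with axis 3 along the beam and axis 1 vertical; rotations are
#' right-hand-rule matrices composed as `R = R3(rot3) R2(rot2) R1(rot1)`;
#' azimuth `chi = atan2(vertical, horizontal)` is zero along the horizontal
#' transverse axis and lies in `(-pi, pi]`.
#'
#' @param det an [detector()].
#' @param dist sample-PONI distance (m), `> 0`.
#' @param poni1,poni2 PONI coordinates in the detector frame (m).
#' @param rot1,rot2,rot3 rotations (radians).
#' @param wavelength X-ray wavelength (m); optional until `q` is requested.
#' @return an object of class `"az_geometry"`.
#' @examples
#' g <- geometry(detector(c(8, 8), 1e-4), dist = 0.1,
#'               poni1 = 4e-4, poni2 = 4e-4, wavelength = 1e-10)
#' pixel_angles(g)$tth[1, 1]
#' @export
geometry <- function(det, dist, poni1 = 0, poni2 = 0,
                     rot1 = 0, rot2 = 0, rot3 = 0, wavelength = NULL) {
  stopifnot(inherits(det, "az_detector"))
  if (!is.finite(dist) || dist <= 0) stop("dist must be a positive finite distance")
  if (!all(is.finite(c(poni1, poni2, rot1, rot2, rot3))))
    stop("geometry parameters must be finite")
  if (!is.null(wavelength) && (!is.finite(wavelength) || wavelength <= 0))
    stop("wavelength must be positive when set")
  structure(list(detector = det, dist = dist, poni1 = poni1, poni2 = poni2,
                 rot1 = rot1, rot2 = rot2, rot3 = rot3,
                 wavelength = wavelength),
            class = "az_geometry")
}

#' @export
print.az_geometry <- function(x, ...) {
  cat(sprintf(paste0("<az_geometry dist=%.6g m, poni=(%.6g, %.6g) m, ",
                     "rot=(%.4g, %.4g, %.4g) rad, lambda=%s>\n"),
              x$dist, x$poni1, x$poni2, x$rot1, x$rot2, x$rot3,
              if (is.null(x$wavelength)) "unset" else sprintf("%.6g m", x$wavelength)))
  print(x$detector)
  invisible(x)
}

geometry_update <- function(geom, params) {
  for (nm in names(params)) geom[[nm]] <- params[[nm]]
  geometry(geom$detector, geom$dist, geom$poni1, geom$poni2,
           geom$rot1, geom$rot2, geom$rot3, geom$wavelength)
}

#' Composed rotation matrix of a geometry
#'
#' `R = R3(rot3) %*% R2(rot2) %*% R1(rot1)`, right-hand-rule rotations about
#' the vertical (1), horizontal (2) and beam (3) lab axes.
#' @param rot1,rot2,rot3 rotation angles (radians).
#' @return a 3x3 matrix.
#' @export
rotation_matrix <- function(rot1, rot2, rot3) {
  c1 <- cos(rot1); s1 <- sin(rot1)
  c2 <- cos(rot2); s2 <- sin(rot2)
  c3 <- cos(rot3); s3 <- sin(rot3)
  R1 <- matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
  R2 <- matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3)
  R3 <- matrix(c(c3, s3, 0, -s3, c3, 0, 0, 0, 1), 3, 3)
  R3 %*% R2 %*% R1
}

#' Detector-frame to lab-frame coordinates
#'
#' Translates detector-frame points by `(-poni1, -poni2, 0)`, appends `dist`
#' along the beam axis, then applies the composed rotation.  With zero
#' rotations the PONI maps to `(0, 0, dist)`.
#'
#' @param geom an [geometry()].
#' @param positions numeric matrix `n x 2` (detector-plane points, third
#'   coordinate 0) or `n x 3`, metres.
#' @return numeric matrix `n x 3` of lab-frame points (metres).
#' @export
lab_coordinates <- function(geom, positions) {
  stopifnot(inherits(geom, "az_geometry"))
  positions <- rbind(positions)  # tolerate a bare vector
  if (!ncol(positions) %in% c(2L, 3L)) stop("positions must have 2 or 3 columns")
  p3 <- if (ncol(positions) == 3) positions[, 3] else 0
  t1 <- positions[, 1] - geom$poni1
  t2 <- positions[, 2] - geom$poni2
  t3 <- geom$dist + p3
  R <- rotation_matrix(geom$rot1, geom$rot2, geom$rot3)
  out <- cbind(t1, t2, t3) %*% t(R)
  dimnames(out) <- NULL
  out
}

.angles_from_lab <- function(lab, wavelength = NULL, dist = NULL) {
  v1 <- lab[, 1]; v2 <- lab[, 2]; v3 <- lab[, 3]
  rho <- sqrt(v1 * v1 + v2 * v2)
  tth <- atan2(rho, v3)
  chi <- atan2(v1, v2)
  chi[chi <= -pi] <- pi
  out <- list(tth = tth, chi = chi)
  if (!is.null(dist)) out$r <- dist * tan(tth)
  if (!is.null(wavelength))
    out$q <- 4 * pi / (wavelength * 1e9) * sin(tth / 2)  # nm^-1
  out
}

#' Per-pixel scattering angles
#'
#' Maps pixel centers (or the four pixel corners) to the scattering angle
#' `tth` (2-theta, radians), azimuth `chi` (radians, `(-pi, pi]`, zero along
#' the horizontal transverse axis), in-plane radius `r = dist * tan(tth)`
#' (metres) and, when the wavelength is set, the scattering-vector magnitude
#' `q = 4 pi sin(tth / 2) / lambda` in inverse nanometres.
#'
#' @param geom an [geometry()].
#' @param at `"centers"` (default, arrays `(Ny, Nx)`) or `"corners"`
#'   (arrays `(Ny, Nx, 4)`).
#' @param need_q error if the wavelength is unset; otherwise `q` is simply
#'   omitted.
#' @return list with elements `tth`, `chi`, `r` and optionally `q`.
#' @export
pixel_angles <- function(geom, at = c("centers", "corners"), need_q = FALSE) {
  stopifnot(inherits(geom, "az_geometry"))
  at <- match.arg(at)
  if (need_q && is.null(geom$wavelength))
    stop("q requested but the geometry has no wavelength")
  pos <- if (at == "centers") pixel_centers(geom$detector) else pixel_corners(geom$detector)
  dm <- dim(pos)
  shp <- dm[-length(dm)]
  m <- matrix(pos, ncol = 3)
  lab <- lab_coordinates(geom, m)
  ang <- .angles_from_lab(lab, geom$wavelength, geom$dist)
  lapply(ang, function(a) array(a, shp))
}

# angles at arbitrary subpixel positions (y, x) in 1-based pixel-center units
point_angles <- function(geom, y, x) {
  det <- geom$detector
  p <- cbind((y - 0.5) * det$pixel1, (x - 0.5) * det$pixel2)
  .angles_from_lab(lab_coordinates(geom, p), geom$wavelength, geom$dist)
}

# inverse mapping: ring angle + azimuth -> subpixel (y, x); NA when the ray
# does not hit the detector plane from the front
ray_to_pixel <- function(geom, tth, chi) {
  v <- cbind(sin(tth) * sin(chi), sin(tth) * cos(chi), cos(tth))
  R <- rotation_matrix(geom$rot1, geom$rot2, geom$rot3)
  u <- v %*% R  # = t(R) applied to each row
  bad <- u[, 3] <= 0
  s <- geom$dist / u[, 3]
  p1 <- geom$poni1 + s * u[, 1]
  p2 <- geom$poni2 + s * u[, 2]
  y <- p1 / geom$detector$pixel1 + 0.5
  x <- p2 / geom$detector$pixel2 + 0.5
  y[bad] <- NA_real_; x[bad] <- NA_real_
  cbind(y = y, x = x)
}

# ---------------------------------------------------------------- PONI files

.poni_keys <- c(Distance = "dist", Poni1 = "poni1", Poni2 = "poni2",
                Rot1 = "rot1", Rot2 = "rot2", Rot3 = "rot3")

#' Read / write PONI geometry files
#'
#' Text format, one `Key: value` per line, `#` comments.  Keys `Distance`,
#' `Poni1`, `Poni2`, `Rot1`, `Rot2`, `Rot3` are mandatory, `Wavelength`
#' optional; all values SI (metres, radians).  A `Detector_config` key holds
#' the detector shape and pixel sizes as JSON so the file is self-contained;
#' alternatively pass `detector`.
#'
#' @param path file path.
#' @param detector optional [detector()] overriding the embedded block.
#' @return `read_poni` returns an [geometry()]; `write_poni` returns `path`
#'   invisibly.
#' @export
read_poni <- function(path, detector = NULL) {
  if (!file.exists(path)) stop("PONI file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- vapply(kv, function(z) trimws(z[1]), "")
  vals <- vapply(kv, function(z) if (length(z) >= 2) trimws(z[2]) else NA_character_, "")
  params <- list()
  for (k in names(.poni_keys)) {
    i <- match(k, keys)
    if (is.na(i)) stop("PONI file ", path, " is missing mandatory key '", k, "'")
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop("PONI key '", k, "' has a non-numeric value: ", vals[i])
    params[[.poni_keys[[k]]]] <- v
  }
  wl <- NULL
  i <- match("Wavelength", keys)
  if (!is.na(i)) {
    wl <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(wl)) stop("PONI key 'Wavelength' has a non-numeric value")
  }
  if (is.null(detector)) {
    i <- match("Detector_config", keys)
    if (is.na(i))
      stop("PONI file ", path, " has no Detector_config and no detector was supplied")
    cfg <- jsonlite::fromJSON(vals[i])
    detector <- detector(as.integer(cfg$shape), cfg$pixel1, cfg$pixel2)
  }
  geometry(detector, params$dist, params$poni1, params$poni2,
           params$rot1, params$rot2, params$rot3, wavelength = wl)
}

#' @rdname read_poni
#' @param geom an [geometry()] to write.
#' @export
write_poni <- function(geom, path) {
  stopifnot(inherits(geom, "az_geometry"))
  det <- geom$detector
  cfg <- jsonlite::toJSON(list(shape = det$shape, pixel1 = det$pixel1,
                               pixel2 = det$pixel2),
                          digits = NA, auto_unbox = FALSE)
  lines <- c("# Calibration file (PONI geometry, SI units)",
             "Detector: flat",
             paste0("Detector_config: ", as.character(cfg)),
             sprintf("Distance: %.17g", geom$dist),
             sprintf("Poni1: %.17g", geom$poni1),
             sprintf("Poni2: %.17g", geom$poni2),
             sprintf("Rot1: %.17g", geom$rot1),
             sprintf("Rot2: %.17g", geom$rot2),
             sprintf("Rot3: %.17g", geom$rot3))
  if (!is.null(geom$wavelength))
    lines <- c(lines, sprintf("Wavelength: %.17g", geom$wavelength))
  writeLines(lines, path)
  invisible(path)
}

# ------------------------------------------------------------- output units

.az_units <- c("2th_rad", "2th_deg", "q_nm^-1", "q_A^-1", "r_m", "r_mm")

# convert an angle list (tth/chi/r/q) into the requested radial unit
unit_coordinate <- function(ang, unit) {
  unit <- match.arg(unit, .az_units)
  switch(unit,
         "2th_rad" = ang$tth,
         "2th_deg" = ang$tth * 180 / pi,
         "q_nm^-1" = { if (is.null(ang$q)) stop("unit q requires a wavelength"); ang$q },
         "q_A^-1"  = { if (is.null(ang$q)) stop("unit q requires a wavelength"); ang$q / 10 },
         "r_m"     = ang$r,
         "r_mm"    = ang$r * 1e3)
}
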