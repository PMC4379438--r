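#' Geometry refinement problem
#'
#' Bundles ring-labelled control points, the calibrant, a starting geometry,
#' the set of free parameters and per-parameter bounds for least-squares
#' refinement of the detector position.
#'
#' Default bounds: `dist` in (1e-6, 10] m, PONI coordinates within one
#' detector extent on either side, rotations in `[-pi/2, pi/2]`, wavelength
#' (when freed) within a factor 2 of the start.  The wavelength is fixed by
#' default: in practice it is known from the monochromator energy, and with a
#' single ring it is perfectly degenerate with the geometry.
#'
#' @param points an [control_points()] object.
#' @param cal an [calibrant()].
#' @param start starting [geometry()].
#' @param free character subset of `c("dist", "poni1", "poni2", "rot1",
#'   "rot2", "rot3", "wavelength")`.
#' @param bounds optional named list of `c(lo, hi)` overriding defaults.
#' @return an object of class `"az_refinement"`.
#' @export
refine_problem <- function(points, cal, start,
                           free = c("dist", "poni1", "poni2",
                                    "rot1", "rot2", "rot3"),
                           bounds = NULL) {
  stopifnot(inherits(points, "az_control_points"),
            inherits(cal, "az_calibrant"), inherits(start, "az_geometry"))
  all_par <- c("dist", "poni1", "poni2", "rot1", "rot2", "rot3", "wavelength")
  if (length(free) == 0) stop("at least one parameter must be free")
  free <- match.arg(free, all_par, several.ok = TRUE)
  wl <- if (!is.null(cal$wavelength)) cal$wavelength else start$wavelength
  if (is.null(wl)) stop("a wavelength is required (calibrant or geometry)")
  rings <- ring_angles(cal, wl)
  if (nrow(points$points) > 0 && max(points$points$ring) > length(rings))
    stop("control points reference ring ", max(points$points$ring),
         " but the calibrant only has ", length(rings), " reachable rings")
  det <- start$detector
  ext1 <- det$shape[1] * det$pixel1; ext2 <- det$shape[2] * det$pixel2
  b <- list(dist = c(1e-6, 10),
            poni1 = c(start$poni1 - ext1, start$poni1 + ext1),
            poni2 = c(start$poni2 - ext2, start$poni2 + ext2),
            rot1 = c(-pi / 2, pi / 2), rot2 = c(-pi / 2, pi / 2),
            rot3 = c(-pi / 2, pi / 2),
            wavelength = c(wl / 2, wl * 2))
  if (!is.null(bounds)) b <- modifyList(b, bounds)
  structure(list(points = points, calibrant = cal, start = start,
                 free = free, bounds = b, wavelength = wl),
            class = "az_refinement")
}

# parameter vector <-> geometry helpers
.problem_params <- function(problem, geom = problem$start) {
  c(dist = geom$dist, poni1 = geom$poni1, poni2 = geom$poni2,
    rot1 = geom$rot1, rot2 = geom$rot2, rot3 = geom$rot3,
    wavelength = if (is.null(geom$wavelength)) problem$wavelength
                 else geom$wavelength)
}

.params_geometry <- function(problem, par) {
  geometry(problem$start$detector, par[["dist"]], par[["poni1"]], par[["poni2"]],
           par[["rot1"]], par[["rot2"]], par[["rot3"]],
           wavelength = par[["wavelength"]])
}

#' Refinement cost
#'
#' Sum over control points of the squared difference between the modelled
#' scattering angle at the (subpixel) point position and the calibrant ring
#' aperture: `sum_i (tth(y_i, x_i; params) - tth_ring(n_i))^2`.  The model
#' angle is obtained by evaluating the geometry transform at the fractional
#' detector-frame coordinate, never by interpolating a precomputed map.
#'
#' @param problem an [refine_problem()].
#' @param params full named parameter vector (see `refine_problem`); defaults
#'   to the starting geometry.
#' @return non-negative scalar.
#' @export
refine_cost <- function(problem, params = .problem_params(problem)) {
  stopifnot(inherits(problem, "az_refinement"))
  geom <- .params_geometry(problem, params)
  pts <- problem$points$points
  rings <- ring_angles(problem$calibrant, params[["wavelength"]])
  tth <- point_angles(geom, pts$y, pts$x)$tth
  sum((tth - rings[pts$ring])^2)
}

#' Refine detector geometry from control points
#'
#' Bounded quasi-Newton (L-BFGS-B) minimisation of [refine_cost()] over the
#' free parameters; fixed parameters are untouched.  Stops when the cost
#' change falls below `1e-12` of the initial cost or after 500 iterations.
#'
#' @param problem an [refine_problem()].
#' @return list with `geometry` (refined), `cost` (final), `initial_cost`,
#'   `residuals` (per-ring data.frame: n, rms and max |d tth| in radians),
#'   `convergence` (optim codes, 0 = converged).
#' @export
refine_geometry <- function(problem) {
  stopifnot(inherits(problem, "az_refinement"))
  pts <- problem$points$points
  free <- problem$free
  if (nrow(pts) < length(free))
    stop("under-determined: ", nrow(pts), " points for ", length(free),
         " free parameters")
  if ("wavelength" %in% free && length(unique(pts$ring)) < 2)
    stop("refining the wavelength needs at least 2 distinct rings ",
         "(single-ring d/lambda scaling is degenerate)")
  p0 <- .problem_params(problem)
  lower <- vapply(free, function(k) problem$bounds[[k]][1], 0)
  upper <- vapply(free, function(k) problem$bounds[[k]][2], 0)
  scale <- pmax(abs(p0[free]),
                c(dist = 1e-2, poni1 = 1e-3, poni2 = 1e-3, rot1 = 1e-2,
                  rot2 = 1e-2, rot3 = 1e-2, wavelength = 1e-10)[free])
  f0 <- refine_cost(problem, p0)
  fn <- function(x) {
    p <- p0
    p[free] <- x
    refine_cost(problem, p)
  }
  opt <- optim(p0[free], fn, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 500, factr = 10,
                              parscale = scale, ndeps = rep(1e-7, length(free)) * scale))
  pfin <- p0
  pfin[free] <- opt$par
  # L-BFGS-B can stop uphill of the start on pathological surfaces; keep start
  if (opt$value > f0) { pfin <- p0; opt$value <- f0 }
  geom <- .params_geometry(problem, pfin)
  rings <- ring_angles(problem$calibrant, pfin[["wavelength"]])
  tth <- point_angles(geom, pts$y, pts$x)$tth
  dev <- tth - rings[pts$ring]
  stats <- do.call(rbind, lapply(split(dev, pts$ring), function(d)
    data.frame(n = length(d), rms = sqrt(mean(d^2)), max_abs = max(abs(d)))))
  stats$ring <- as.integer(rownames(stats))
  .azir_log(sprintf("refine: cost %.4g -> %.4g (%d points, conv=%d)",
                    f0, opt$value, nrow(pts), opt$convergence))
  list(geometry = geom, cost = opt$value, initial_cost = f0,
       residuals = stats[, c("ring", "n", "rms", "max_abs")],
       convergence = opt$convergence)
}

#' Recalibrate a geometry from a ring image
#'
#' Two-round recalibration: extract ring-labelled keypoints under the
#' approximate geometry ([extract_for_rings()]), refine, re-extract with the
#' tolerance tightened to `tol/2` under the refined geometry, refine again.
#'
#' @param img numeric matrix (calibration image).
#' @param geom approximate starting [geometry()].
#' @param cal [calibrant()] with wavelength.
#' @param tol initial ring-assignment tolerance (radians of 2-theta).
#' @param mask optional logical matrix.
#' @param free free parameters, as in [refine_problem()].
#' @param threshold DoG threshold forwarded to [extract_for_rings()].
#' @return list with `geometry`, `points` (final control points), `rounds`
#'   (per-round cost summaries) and `residuals`.
#' @export
recalibrate <- function(img, geom, cal, tol = 5e-3, mask = NULL,
                        free = c("dist", "poni1", "poni2", "rot1", "rot2", "rot3"),
                        threshold = NULL) {
  cur <- geom
  rounds <- list()
  cps <- NULL
  last <- NULL
  for (round in 1:2) {
    cps <- extract_for_rings(img, cur, cal, tol_tth = tol, mask = mask,
                             threshold = threshold)
    prob <- refine_problem(cps, cal, cur, free = free)
    last <- refine_geometry(prob)
    cur <- last$geometry
    rounds[[round]] <- data.frame(round = round, n_points = nrow(cps$points),
                                  tol = tol, initial_cost = last$initial_cost,
                                  cost = last$cost)
    tol <- tol / 2
  }
  list(geometry = cur, points = cps, rounds = do.call(rbind, rounds),
       residuals = last$residuals)
}
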