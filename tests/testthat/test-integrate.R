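test_that("corrections follow the stated formulas", {
  g <- std_geometry(32)
  img <- matrix(runif(32 * 32, 1, 2), 32)
  expect_true(all(apply_corrections(img, g, dark = img)$signal == 0))
  # solid angle is 1 at the PONI and cos^3 off-normal
  det <- detector(c(1, 1), 2e-4)
  g0 <- geometry(det, dist = 0.1, poni1 = 1e-4, poni2 = 1e-4)
  expect_equal(solid_angle_map(g0)[1, 1], 1)
  g45 <- geometry(det, dist = 0.1, poni1 = 1e-4 + 0.1, poni2 = 1e-4)
  expect_equal(solid_angle_map(g45)[1, 1], cos(pi / 4)^3, tolerance = 1e-12)
  # flat with zeros rejected; dummy pixels dynamically masked
  expect_error(apply_corrections(img, g, flat = matrix(0, 32, 32)), "zeros")
  img2 <- img; img2[3, 7] <- -10
  cm <- apply_corrections(img2, g, dummy = -10)
  expect_true(cm$mask[3, 7])
  expect_equal(sum(cm$mask), 1)
  # polarization factor: P = (1 + cos^2 tth - f cos(2 chi) sin^2 tth) / 2
  gp <- std_geometry(16)
  ang <- pixel_angles(gp)
  f <- 0.95
  got <- apply_corrections(matrix(1, 16, 16), gp, polarization_factor = f)$signal
  P <- 0.5 * (1 + cos(ang$tth)^2 - f * cos(2 * ang$chi) * sin(ang$tth)^2)
  expect_equal(got, 1 / P, tolerance = 1e-12)
})

test_that("bbox fractions are separable overlap products", {
  grid <- bin_grid(4, c(0, 1), "2th_rad", npt_azim = 1)
  inside <- bbox_fractions(c(0.30, 0.30, 0.45, 0.45), c(0.1, 0.2, 0.2, 0.1), grid)
  expect_equal(inside$frac, 1)
  expect_equal(inside$bin_rad, 2L)
  strad <- bbox_fractions(c(0.20, 0.20, 0.30, 0.30), c(0.1, 0.2, 0.2, 0.1), grid)
  expect_equal(sort(strad$frac), c(0.5, 0.5))
  # random boxes against the dense rasterization oracle
  set.seed(61)
  grid2 <- bin_grid(5, c(0, 1), "2th_rad", npt_azim = 6)
  for (rep in 1:20) {
    u0 <- runif(1, 0, 0.8); u1 <- u0 + runif(1, 0.05, 0.2)
    a0 <- runif(1, -2.5, 1.5); a1 <- a0 + runif(1, 0.1, 1)
    fr <- bbox_fractions(c(u0, u0, u1, u1), c(a0, a1, a1, a0), grid2)
    expect_equal(sum(fr$frac), 1, tolerance = 1e-9)
    oracle <- oracle_box_fractions(u0, u1, a0, a1, grid2$radial_edges,
                                   grid2$azim_edges)
    for (k in seq_len(nrow(fr)))
      expect_lt(abs(fr$frac[k] - oracle[fr$bin_rad[k], fr$bin_azim[k]]), 2e-3)
  }
})

test_that("polygon fractions match geometry and the Monte-Carlo oracle", {
  grid <- bin_grid(4, c(0, 4), "2th_rad", npt_azim = 1)
  sq <- polygon_fractions(c(1.2, 1.2, 1.8, 1.8), c(0, 1, 1, 0), grid)
  expect_equal(sq$frac, 1)
  halves <- polygon_fractions(c(0.5, 0.5, 1.5, 1.5), c(0, 1, 1, 0), grid)
  expect_equal(sort(halves$frac), c(0.5, 0.5))
  # 45-degree rotated square centered on a 2x2 grid cross
  g22 <- bin_grid(2, c(-1, 1), "2th_rad", npt_azim = 2)
  rot <- polygon_fractions(c(0, 0.5, 0, -0.5), c(1, 0, -1, 0), g22)
  expect_equal(rot$frac, rep(0.25, 4))
  expect_error(polygon_fractions(c(0, 1, 0, 1), c(0, 1, 1, 0), grid),
               "self-intersecting")
  # random quads vs Monte-Carlo within 3 binomial sigmas (plus MC-zero slack)
  set.seed(62)
  grid2 <- bin_grid(5, c(0, 1), "2th_rad", npt_azim = 5)
  for (rep in 1:25) {
    # strictly inside the grid, so fractions must sum to 1
    th <- sort(runif(4, 0, 2 * pi))
    qu <- runif(1, 0.35, 0.65) + runif(1, 0.05, 0.3) * cos(th)
    qa <- runif(1, -1.8, 1.8) + runif(1, 0.1, 1) * sin(th)
    fr <- polygon_fractions(qu, qa, grid2)
    expect_equal(sum(fr$frac), 1, tolerance = 1e-9)
    mc <- oracle_mc_quad(qu, qa, grid2$radial_edges, grid2$azim_edges, n = 1e4)
    for (k in seq_len(nrow(fr))) {
      inbin <- mc$inside & mc$iu == fr$bin_rad[k] & mc$ia == fr$bin_azim[k]
      p <- sum(inbin) / mc$n_in
      se <- sqrt(max(p * (1 - p), 1e-4) / mc$n_in)
      expect_lt(abs(fr$frac[k] - p), 3 * se + 3e-3)
    }
  }
})

test_that("rebinner coefficients conserve pixels and honour masks", {
  g <- std_geometry(64)
  coords_rng <- range(pixel_angles(g, at = "corners")$tth)
  grid <- bin_grid(50, coords_rng, "2th_rad", npt_azim = 1)
  mask <- matrix(FALSE, 64, 64); mask[10, 11] <- TRUE
  for (scheme in c("nosplit", "bbox", "fullsplit")) {
    reb <- build_rebinner(g, grid, scheme, mask = mask)
    rs <- Matrix::rowSums(reb$matrix)
    expect_true(all(abs(rs[rs > 0.5] - 1) < 1e-9))
    # masked pixel has an empty row
    expect_equal(rs[(11 - 1) * 64 + 10], 0)
    if (scheme == "nosplit") {
      # exactly one unit coefficient per unmasked pixel
      expect_true(all(reb$matrix@x == 1))
      expect_equal(sum(rs), 64 * 64 - 1)
    } else {
      # all pixels interior to the corner-spanning grid: total weight = npix
      expect_equal(sum(rs), 64 * 64 - 1, tolerance = 1e-6)
    }
    # CSR layout is consistent with the matrix
    expect_equal(length(reb$csr$coef), length(reb$matrix@x))
    expect_equal(reb$csr$row_ptr[length(reb$csr$row_ptr)],
                 length(reb$csr$coef))
  }
})

test_that("direct histogramming and CSR rebinning agree to 1e-10", {
  g <- std_geometry(64, rot1 = 0.03, rot2 = -0.02)
  set.seed(63)
  img <- matrix(runif(64 * 64, 0, 100), 64)
  for (scheme in c("nosplit", "bbox", "fullsplit")) {
    d <- integrate1d(img, g, npt = 40, unit = "2th_rad", scheme = scheme,
                     method = "direct", error_model = "poisson")
    c_ <- integrate1d(img, g, npt = 40, unit = "2th_rad", scheme = scheme,
                      method = "csr", error_model = "poisson")
    ok <- is.finite(c_$intensity)
    expect_identical(ok, is.finite(d$intensity))
    expect_lt(max(abs(d$intensity[ok] - c_$intensity[ok]) /
                  pmax(abs(c_$intensity[ok]), 1e-300)), 1e-10)
    expect_lt(max(abs(d$sigma[ok] - c_$sigma[ok]) /
                  pmax(c_$sigma[ok], 1e-300)), 1e-10)
    expect_equal(d$weight, c_$weight, tolerance = 1e-12)
    expect_identical(d$count, c_$count)
    # 2-D as well
    d2 <- integrate2d(img, g, npt_rad = 20, npt_azim = 18, unit = "2th_rad",
                      scheme = scheme, method = "direct")
    c2 <- integrate2d(img, g, npt_rad = 20, npt_azim = 18, unit = "2th_rad",
                      scheme = scheme, method = "csr")
    ok2 <- is.finite(c2$intensity)
    expect_lt(max(abs(d2$intensity[ok2] - c2$intensity[ok2]) /
                  pmax(abs(c2$intensity[ok2]), 1e-300)), 1e-10)
  }
})

test_that("constant images integrate to the constant under every scheme", {
  g <- std_geometry(48)
  img <- matrix(7.25, 48, 48)
  for (scheme in c("nosplit", "bbox", "fullsplit"))
    for (method in c("csr", "direct")) {
      res <- integrate1d(img, g, npt = 25, scheme = scheme, method = method)
      expect_true(all(abs(res$intensity[res$count > 0] - 7.25) < 1e-10))
      expect_true(all(is.nan(res$intensity[res$count == 0])))
    }
})

test_that("integrate1d round-trips a smooth calcfrom1d pattern to 1%", {
  g <- std_geometry()
  fix <- smooth_isotropic(g)
  res <- integrate1d(fix$image, g, npt = 2000, unit = "2th_rad",
                     scheme = "fullsplit")
  want <- approx(fix$grid, fix$pattern, xout = res$radial)$y
  interior <- res$radial > min(fix$grid) + 0.005 &
              res$radial < max(fix$grid) - 0.005 & is.finite(res$intensity)
  expect_lt(max(abs(res$intensity[interior] - want[interior]) /
                want[interior]), 1e-2)
})

test_that("2-D integration marginalises to 1-D and respects support", {
  g <- std_geometry(96)
  set.seed(64)
  img <- matrix(runif(96 * 96, 0, 10), 96)
  rng <- range(pixel_angles(g, at = "corners")$tth)
  r1 <- integrate1d(img, g, npt = 30, unit = "2th_rad", scheme = "fullsplit",
                    radial_range = rng)
  r2 <- integrate2d(img, g, npt_rad = 30, npt_azim = 36, unit = "2th_rad",
                    scheme = "fullsplit", radial_range = rng)
  w <- r2$weight; I <- r2$intensity
  I[!is.finite(I)] <- 0
  marg <- rowSums(I * w) / rowSums(w)
  ok <- is.finite(r1$intensity)
  expect_lt(max(abs(marg[ok] - r1$intensity[ok]) / abs(r1$intensity[ok])), 1e-10)
  # image supported only in the upper half-plane (chi > 0 <=> axis-1 above
  # PONI): lower-half bins away from the chi = 0 / +-pi boundaries and from
  # the PONI (where single pixels legitimately span many azimuth bins) see
  # zero signal
  ctr <- pixel_centers(g$detector)
  upper <- ctr[, , 1] > g$poni1
  img2 <- img; img2[!upper] <- 0
  r3 <- integrate2d(img2, g, npt_rad = 20, npt_azim = 8, unit = "2th_rad")
  halfw <- pi / 8  # half an azimuthal bin
  lower_cols <- which(r3$azimuth - halfw > -pi + 0.3 & r3$azimuth + halfw < -0.3)
  vals <- r3$intensity[-(1:2), lower_cols]
  expect_true(all(!is.finite(vals) | abs(vals) < 1e-12))
})

test_that("error models propagate variance as documented", {
  # single pixel, coefficient 1: sigma = sqrt(v)
  det <- detector(c(3, 3), 1e-4)
  g <- geometry(det, dist = 0.05, poni1 = 1.5e-4, poni2 = 1.5e-4)
  img <- matrix(4, 3, 3)
  v <- matrix(9, 3, 3)
  res <- integrate1d(img, g, npt = 3, unit = "2th_rad", scheme = "nosplit",
                     error_model = "variance", variance = v)
  one <- which(res$count == 1)
  expect_true(all(abs(res$sigma[one] - 3) < 1e-12))
  # N equal pixels with variance v in one bin: sigma = sqrt(v / N)
  resN <- integrate1d(img, g, npt = 1, unit = "2th_rad", scheme = "nosplit",
                      error_model = "poisson")
  expect_equal(resN$count, 9L)
  expect_equal(resN$sigma, sqrt(4 / 9), tolerance = 1e-12)
  # azimuthal model on a constant image: zero spread
  g2 <- std_geometry(32)
  resA <- integrate1d(matrix(5, 32, 32), g2, npt = 10, unit = "2th_rad",
                      scheme = "nosplit", error_model = "azimuthal")
  expect_true(all(resA$sigma[resA$count > 1] < 1e-10))
  # negative raw counts are clipped with a warning under poisson
  imgn <- matrix(4, 3, 3); imgn[2, 2] <- -5
  expect_warning(integrate1d(imgn, g, npt = 3, unit = "2th_rad",
                             error_model = "poisson"), "clipped")
})

test_that("schemes converge on coarse bins and order by smoothness", {
  g <- std_geometry()
  fix <- smooth_isotropic(g)
  res <- lapply(c("nosplit", "bbox", "fullsplit"), function(s)
    integrate1d(fix$image, g, npt = 8, unit = "2th_rad", scheme = s,
                radial_range = range(pixel_angles(g, at = "corners")$tth)))
  ok <- Reduce(`&`, lapply(res, function(r) is.finite(r$intensity)))
  ref <- res[[3]]$intensity[ok]
  for (r in res[1:2])
    expect_lt(max(abs(r$intensity[ok] - ref) / abs(ref)), 1e-3)
  # total variation ordering on a spotty image, fine bins
  sp <- spotty_rings_image(std_calibrant(), g, n_spots_per_ring = 25,
                           spot_sigma = 2, seed = 65)
  tv <- vapply(c("nosplit", "bbox", "fullsplit"), function(s) {
    r <- integrate1d(sp$image, g, npt = 500, unit = "2th_rad", scheme = s)
    i <- r$intensity; i[!is.finite(i)] <- 0
    sum(abs(diff(i)))
  }, 0)
  # splitting smooths: both split schemes sit well under the histogram; the
  # bounding box is a superset of the pixel quad, so bbox can be marginally
  # smoother than fullsplit - the two agree within a few percent
  expect_lt(tv[["fullsplit"]], tv[["nosplit"]])
  expect_lt(tv[["bbox"]], tv[["nosplit"]])
  expect_lt(abs(tv[["fullsplit"]] - tv[["bbox"]]) / tv[["bbox"]], 0.05)
})

test_that("masking a pixel equals deleting its coefficients", {
  g <- std_geometry(48)
  set.seed(66)
  img <- matrix(runif(48 * 48), 48)
  mask <- matrix(FALSE, 48, 48); mask[c(100, 777, 1500)] <- TRUE
  for (scheme in c("bbox", "fullsplit")) {
    rng <- range(pixel_angles(g, at = "corners")$tth)
    grid <- bin_grid(30, rng, "2th_rad")
    reb_full <- build_rebinner(g, grid, scheme)
    reb_mask <- build_rebinner(g, grid, scheme, mask = mask)
    A <- reb_full$matrix
    A[as.vector(mask), ] <- 0
    expect_equal(as.matrix(A), as.matrix(reb_mask$matrix), tolerance = 0)
    r1 <- integrate1d(img, g, npt = 30, unit = "2th_rad", scheme = scheme,
                      mask = mask, radial_range = rng)
    r2 <- integrate1d(img, g, npt = 30, unit = "2th_rad", scheme = scheme,
                      rebinner = reb_mask)
    expect_equal(r1$intensity, r2$intensity)
  }
})

test_that("pattern files round-trip through the ASCII format", {
  g <- std_geometry(32)
  res <- integrate1d(matrix(runif(32 * 32), 32), g, npt = 20,
                     error_model = "azimuthal")
  path <- withr::local_tempfile(fileext = ".dat")
  write_pattern(res, path, extra = c(seed = "7"))
  back <- read_pattern(path)
  ok <- is.finite(res$intensity)
  expect_equal(back$radial, res$radial)
  expect_equal(back$intensity[ok], res$intensity[ok])
  expect_equal(back$sigma[ok], res$sigma[ok])
  hdr <- readLines(path, n = 10)
  expect_true(any(grepl("# seed: 7", hdr)))
})
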