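test_that("subpixel refinement is exact on quadratic surfaces", {
  yy <- outer(1:30, rep(1, 30)); xx <- t(yy)
  img <- 50 - 0.7 * (yy - 10.3)^2 - 1.3 * (xx - 20.7)^2
  r <- refine_subpixel(img, c(10, 21))
  expect_equal(as.vector(r), c(10.3, 20.7), tolerance = 1e-12)
  expect_false(attr(r, "fallback"))
  # symmetric peak centered on a grid point: delta = 0
  img2 <- render_gaussian(21, 21, 11, 11, 2)
  r2 <- refine_subpixel(img2, c(11, 11))
  expect_equal(as.vector(r2), c(11, 11), tolerance = 1e-12)
  expect_error(refine_subpixel(img, c(1, 5)), "border")
})

test_that("centre-of-mass fallback triggers exactly when |delta| > 1", {
  # engineered patch: gx = 0.95, hxx = -0.1 -> Newton step 9.5 -> fallback
  patch <- rbind(c(0, 0.5, 0),
                 c(0, 1.0, 1.9),
                 c(0, 0.5, 0))
  img <- matrix(0, 5, 5)
  img[2:4, 2:4] <- patch
  r <- refine_subpixel(img, c(3, 3))
  expect_true(attr(r, "fallback"))
  w <- pmax(img[2:4, 2:4], 0)
  com <- c(3 + sum(w * c(-1, 0, 1)) / sum(w),
           3 + sum(t(w) * c(-1, 0, 1)) / sum(w))
  expect_equal(as.vector(r), com, tolerance = 1e-12)
  expect_true(all(abs(as.vector(r) - c(3, 3)) <= 1))
  # a clean quadratic with |delta| < 1 must NOT fall back
  yy <- outer(1:9, rep(1, 9)); xx <- t(yy)
  q <- 10 - (yy - 5.45)^2 - (xx - 4.6)^2
  expect_false(attr(refine_subpixel(q, c(5, 5)), "fallback"))
})

test_that("refine_subpixel is equivariant under translation and transposition", {
  set.seed(41)
  img <- render_gaussian(40, 40, 17.37, 22.81, 2.5)
  base <- refine_subpixel(img, c(17, 23))
  shifted <- matrix(0, 40, 40)
  shifted[6:40, 1:35] <- img[1:35, 6:40]  # translate by (+5, -5) whole pixels
  r2 <- refine_subpixel(shifted, c(22, 18))
  expect_equal(as.vector(r2), as.vector(base) + c(5, -5), tolerance = 1e-10)
  r3 <- refine_subpixel(t(img), c(23, 17))
  expect_equal(as.vector(r3), rev(as.vector(base)), tolerance = 1e-12)
})

test_that("massif extraction separates rings from background", {
  expect_equal(nrow(massif_extract(matrix(5, 64, 64))$peaks), 0)
  expect_equal(max(massif_extract(matrix(5, 64, 64))$labels), 0)
  expect_error(massif_extract(matrix(1, 4, 4), mask = matrix(TRUE, 4, 4)),
               "masked")
  # single Gaussian spot on zero background: one region holding the maximum
  img <- render_gaussian(64, 64, 30.2, 40.6, 3)
  me <- massif_extract(img, sigma = 5)
  expect_equal(max(me$labels), 1)
  expect_equal(nrow(me$peaks), 1)
  expect_lt(sqrt((me$peaks$y - 30.2)^2 + (me$peaks$x - 40.6)^2), 0.5)
})

test_that("massif peaks on the spotty fixture recover truth and group by ring", {
  g <- std_geometry()
  cal <- std_calibrant()
  sp <- spotty_rings_image(cal, g, n_spots_per_ring = 12, spot_sigma = 2,
                           seed = 42)
  me <- massif_extract(sp$image, sigma = 6)
  pk <- me$peaks[me$peaks$intensity > 0.05 * max(sp$image), ]
  expect_gt(nrow(pk), 0.8 * nrow(sp$spots))
  d2 <- outer(pk$y, sp$spots$y, "-")^2 + outer(pk$x, sp$spots$x, "-")^2
  nearest <- sqrt(apply(d2, 1, min))
  expect_gte(mean(nearest < 1), 0.95)
  # peaks sharing a region share a ring: 2-theta spread within a region
  rings <- ring_angles(cal)
  spacing <- min(diff(rings))
  tth <- azir:::point_angles(g, pk$y, pk$x)$tth
  for (reg in unique(pk$region)) {
    s <- tth[pk$region == reg]
    if (length(s) > 1) expect_lt(diff(range(s)), spacing / 2)
  }
})

test_that("massif regions are invariant to constant offsets and merge with sigma", {
  g <- std_geometry()
  sp <- spotty_rings_image(std_calibrant(), g, n_spots_per_ring = 12,
                           spot_sigma = 2, seed = 43)
  m1 <- massif_extract(sp$image, sigma = 6)
  m2 <- massif_extract(sp$image + 100, sigma = 6)
  expect_identical(m1$labels > 0, m2$labels > 0)
  nreg <- vapply(c(4, 8, 16, 32), function(s)
    max(massif_extract(sp$image, sigma = s)$labels), 0L)
  expect_true(all(diff(nreg) <= 0))
})

test_that("blob detection finds an isolated blob once, at the right scale", {
  expect_equal(nrow(blob_detect(matrix(3, 64, 64))), 0)
  img <- render_gaussian(96, 96, 40.3, 57.7, 4)
  kp <- blob_detect(img, threshold = 1)
  expect_equal(nrow(kp), 1)
  expect_lt(sqrt((kp$y - 40.3)^2 + (kp$x - 57.7)^2), 0.5)
  opt <- oracle_dog_optimum(img, 40.3, 57.7)
  expect_lt(abs(log(kp$sigma / opt)), log(sqrt(2)) + 1e-6)
})

test_that("peaks below the ~3 px width floor are not detected", {
  # FWHM 2 px (sigma 0.85): under the documented floor
  img <- render_gaussian(64, 64, 31.4, 33.6, 2 / 2.3548)
  expect_equal(nrow(blob_detect(img, threshold = 1)), 0)
  # FWHM 6 px is comfortably above the floor
  img2 <- render_gaussian(64, 64, 31.4, 33.6, 6 / 2.3548)
  expect_gte(nrow(blob_detect(img2, threshold = 1)), 1)
})

test_that("blob positions agree across a 2x resolution change", {
  y0 <- 30.3; x0 <- 40.7
  img1 <- render_gaussian(96, 96, y0, x0, 4)
  img2 <- render_gaussian(192, 192, 2 * y0 - 0.5, 2 * x0 - 0.5, 8)
  k1 <- blob_detect(img1, threshold = 1)
  k2 <- blob_detect(img2, threshold = 1)
  expect_equal(nrow(k1), 1)
  expect_gte(nrow(k2), 1)
  k2 <- k2[which.max(k2$intensity), ]
  # map fine-grid detection back to coarse coordinates
  expect_lt(abs((k2$y + 0.5) / 2 - k1$y), 0.5)
  expect_lt(abs((k2$x + 0.5) / 2 - k1$x), 0.5)
})

test_that("masked regions neither blur into keypoints nor keep their own", {
  img <- render_gaussian(96, 96, 40.3, 57.7, 4)
  mask <- matrix(FALSE, 96, 96)
  mask[39:42, 56:60] <- TRUE   # mask the blob itself
  kp <- blob_detect(img, mask = mask, threshold = 1)
  expect_equal(nrow(kp), 0)
})

test_that("extract_for_rings assigns keypoints to their generating ring", {
  g <- std_geometry()
  cal <- std_calibrant()
  # one pixel spans 2 mrad here, so W = (8 mrad)^2 gives 4 px wide rings,
  # comfortably above the blob-detection width floor
  img <- fake_calibration_image(cal, g, caglioti(W = (8e-3)^2), Imax = 1e4,
                                poisson_noise = TRUE, seed = 44)
  rings <- ring_angles(cal)
  tol <- min(diff(rings)) / 2
  cps <- extract_for_rings(img, g, cal, tol_tth = tol)
  expect_gt(nrow(cps$points), 100)
  tth <- azir:::point_angles(g, cps$points$y, cps$points$x)$tth
  truth_ring <- vapply(tth, function(t) which.min(abs(rings - t)), 1L)
  expect_identical(cps$points$ring, truth_ring)
  expect_error(extract_for_rings(img, g, cal, tol_tth = 0), "positive")
  # a geometry perturbation well under tol/2 leaves assignments unchanged
  g2 <- geometry(g$detector, g$dist * 1.001, g$poni1 + 2e-5, g$poni2,
                 g$rot1, g$rot2, g$rot3, g$wavelength)
  cps2 <- extract_for_rings(img, g2, cal, tol_tth = tol)
  common <- merge(cps$points, cps2$points, by = c("y", "x"))
  expect_gt(nrow(common), 0.9 * nrow(cps$points))
  expect_identical(common$ring.x, common$ring.y)
})

test_that("control point files round-trip", {
  cps <- control_points(data.frame(ring = c(2L, 1L, 2L),
                                   y = c(10.25, 3.5, 40.125),
                                   x = c(7.75, 8.5, 9.0625)), c(64L, 64L))
  path <- withr::local_tempfile(fileext = ".txt")
  write_control_points(cps, path)
  back <- read_control_points(path)
  expect_equal(back$points, cps$points, ignore_attr = TRUE)
  expect_identical(back$shape, cps$shape)
  expect_error(control_points(data.frame(ring = 1L, y = -3, x = 2), c(8L, 8L)),
               "bounds")
  expect_error(control_points(data.frame(ring = 0L, y = 3, x = 2), c(8L, 8L)),
               "ring")
})
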