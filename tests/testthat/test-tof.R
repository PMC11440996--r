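test_that("timing-to-position conversions match their closed forms", {
  # 385 ps FWHM corresponds to 57.7 mm along the LOR at one decimal
  expect_equal(round(fwhmPsToMm(385), 1), 57.7)
  expect_equal(fwhmPsToMm(385), 385e-12 * 299792458 / 2 * 1e3)
  # 169 ps -> 25.33 mm with the exact speed of light
  expect_equal(round(fwhmPsToMm(169), 2), 25.33)
  expect_error(fwhmPsToMm(0), "positive")
  expect_error(fwhmPsToMm(-1), "positive")
  expect_equal(sigmaFromFwhm(2 * sqrt(2 * log(2))), 1.0)
  expect_equal(sigmaFromFwhm(57.71), 24.51, tolerance = 1e-3)
  f <- 42.7
  expect_equal(sigmaFromFwhm(f) * 2 * sqrt(2 * log(2)), f)
  expect_error(sigmaFromFwhm(0), "positive")
})

test_that("TOF bin weight matches Gaussian-over-bin quadrature and is symmetric", {
  spec <- tofSpec(29, 25.35, 24.51)
  d <- c(-rev(seq(0.9, 80, by = 7.3)), 0, seq(0.9, 80, by = 7.3))
  w <- tofBinWeight(d, spec)
  expect_equal(w, rev(w)) # symmetry: weight(d) = weight(-d)
  # quadrature oracle: integrate the Gaussian density over [d-w/2, d+w/2]
  for (dd in c(0, 5.2, -17.9, 40)) {
    q <- stats::integrate(function(u) stats::dnorm(u, dd, 24.51),
                          -25.35 / 2, 25.35 / 2, rel.tol = 1e-12)$value
    expect_lt(abs(tofBinWeight(dd, spec) - q), 1e-10)
  }
  # truncation: exactly zero beyond n_sigmas*sigma + w/2
  cutoff <- 3 * 24.51 + 25.35 / 2
  expect_identical(tofBinWeight(cutoff + 1e-9, spec), 0)
  expect_gt(tofBinWeight(cutoff - 1e-6, spec), 0)
  # an unbounded bin grid forms a partition of unity
  spec6 <- tofSpec(29, 25.35, 24.51, nSigmas = 8)
  for (dd in c(0, 3.7, -11)) {
    s <- sum(tofBinWeight(dd - (-40:40) * 25.35, spec6))
    expect_lt(abs(s - 1), 1e-6)
  }
  # bin-width -> infinity limit captures all mass
  wide <- tofSpec(1, 1e9, 10)
  expect_equal(tofBinWeight(0, wide), 1)
})

test_that("a huge single TOF bin degenerates to the non-TOF projection", {
  g <- imageGrid(c(8, 8, 8), 2)
  img <- smoothImage(g, seed = 1)
  rays <- sphereRays(25, radius = 25, seed = 1)
  spec <- tofSpec(1, 1e7, 1e6)
  ft <- forwardProjectTOF(img, g, rays, spec)
  expect_equal(ncol(ft), 1L)
  f0 <- forwardProject(img, g, rays)
  expect_lt(max(relErr(ft[, 1], f0)), 1e-6)
})

test_that("summing TOF bins reproduces the non-TOF projection", {
  g <- imageGrid(c(8, 8, 8), 2)
  img <- smoothImage(g, seed = 6)
  rays <- sphereRays(30, radius = 25, seed = 6)
  # bin grid spans the in-FOV segment (|midpoint offset| <= 14 mm) plus
  # 3 sigma + w/2 margins
  spec <- tofSpec(15, 6, 4)
  ft <- forwardProjectTOF(img, g, rays, spec)
  f0 <- forwardProject(img, g, rays)
  expect_lt(max(relErr(rowSums(ft), f0)), 1e-3)
})

test_that("a point source produces the TOF kernel profile across bins", {
  g <- imageGrid(c(9, 9, 9), 2) # voxel (4,4,4) centered at the origin
  img <- array(0, gridShape(g))
  img[5, 5, 5] <- 1
  spec <- tofSpec(11, 5, 4)
  # asymmetric endpoints: midpoint at x = +20, so the voxel sits at signed
  # distance -20 mm from the LOR midpoint
  rays <- raySet(matrix(c(-30, 0, 0), 1), matrix(c(70, 0, 0), 1))
  prof <- forwardProjectTOF(img, g, rays, spec)[1, ]
  f0 <- forwardProject(img, g, rays)
  expected <- f0 * tofBinWeight(-20 - tofBinCenters(spec), spec)
  expect_equal(prof, expected, tolerance = 1e-12)
})

test_that("listmode TOF values equal the matching sinogram bin", {
  g <- imageGrid(c(8, 8, 8), c(2, 1.5, 2.5))
  img <- smoothImage(g, seed = 8)
  rays <- sphereRays(40, radius = 25, seed = 8)
  spec <- tofSpec(9, 6, 5)
  ft <- forwardProjectTOF(img, g, rays, spec)
  set.seed(8)
  sb <- sample(-4:4, 40, replace = TRUE)
  fl <- forwardProjectTOFLm(img, g, rays, sb, spec)
  expect_lt(max(relErr(fl, ft[cbind(1:40, sb + 5)])), 1e-12)
  # zero image and out-of-segment bins
  expect_equal(forwardProjectTOFLm(array(0, gridShape(g)), g, rays, sb, spec),
               numeric(40))
  far <- raySet(matrix(c(-100, 0, 0), 1), matrix(c(100, 0, 0), 1))
  # bin centered 4*6=24 mm + margins beyond the in-FOV segment end
  expect_equal(forwardProjectTOFLm(img, g, far, 4L, tofSpec(9, 6, 1)), 0)
  expect_error(forwardProjectTOFLm(img, g, rays, rep(5L, 40), spec),
               "out of range")
})

test_that("TOF back projectors are exact adjoints (sinogram and listmode)", {
  worst_s <- worst_l <- 0
  for (cfg in list(list(shape = c(8, 8, 8), vox = c(2, 2, 2)),
                   list(shape = c(12, 9, 10), vox = c(1.5, 2.5, 3)))) {
    g <- imageGrid(cfg$shape, cfg$vox)
    set.seed(13)
    x <- array(runif(prod(cfg$shape)), cfg$shape)
    spec <- tofSpec(9, 6, 5)
    for (axis in 1:3) {
      rays <- axisRays(30, axis, radius = 50, seed = 3)
      ys <- matrix(runif(30 * 9), 30)
      lhs <- sum(forwardProjectTOF(x, g, rays, spec) * ys)
      rhs <- sum(x * backProjectTOF(ys, rays, g, spec))
      worst_s <- max(worst_s, abs(lhs - rhs) / (abs(lhs) + 1e-12))
      sb <- sample(-4:4, 30, replace = TRUE)
      yl <- runif(30)
      lhs <- sum(forwardProjectTOFLm(x, g, rays, sb, spec) * yl)
      rhs <- sum(x * backProjectTOFLm(yl, rays, sb, g, spec))
      worst_l <- max(worst_l, abs(lhs - rhs) / (abs(lhs) + 1e-12))
    }
  }
  expect_lt(worst_s, 1e-12)
  expect_lt(worst_l, 1e-12)
})

test_that("TOF sinogram pair matches the dense oracle and zero maps to zero", {
  g <- imageGrid(c(8, 8, 8), 2)
  set.seed(21)
  img <- array(runif(512), gridShape(g))
  rays <- sphereRays(12, radius = 25, seed = 21)
  spec <- tofSpec(5, 8, 6)
  A <- denseForwardMatrix(g, rays, tof = spec)
  ft <- forwardProjectTOF(img, g, rays, spec)
  expect_lt(max(abs(as.vector(ft) - A %*% as.vector(img))),
            1e-10 * max(abs(ft)))
  y <- matrix(runif(12 * 5), 12)
  bt <- backProjectTOF(y, rays, g, spec)
  expect_lt(max(abs(as.vector(bt) - as.vector(t(A) %*% as.vector(y)))),
            1e-10 * max(abs(bt)))
  expect_equal(backProjectTOF(matrix(0, 12, 5), rays, g, spec),
               array(0, gridShape(g)))
  # single event equals the matching single-bin sinogram back projection
  r1 <- raySet(rays@start[3, , drop = FALSE], rays@end[3, , drop = FALSE])
  ysin <- matrix(0, 1, 5)
  ysin[1, 4] <- 2.5 # signed bin +1
  b_s <- backProjectTOF(ysin, r1, g, spec)
  b_l <- backProjectTOFLm(2.5, r1, 1L, g, spec)
  expect_equal(b_l, b_s, tolerance = 1e-14)
})

test_that("widening truncation from 3 to 6 sigma changes values by < 0.3%", {
  g <- imageGrid(c(8, 8, 8), 2)
  img <- smoothImage(g, seed = 14)
  rays <- sphereRays(30, radius = 25, seed = 14)
  f3 <- forwardProjectTOF(img, g, rays, tofSpec(9, 6, 5, nSigmas = 3))
  f6 <- forwardProjectTOF(img, g, rays, tofSpec(9, 6, 5, nSigmas = 6))
  expect_true(all(f6 - f3 > -1e-14)) # non-decreasing for non-negative images
  # the added weight is at most the kernel mass beyond 3 sigma (~0.27%)
  # of the ray's total line integral
  f0 <- forwardProject(img, g, rays)
  expect_lt(max((f6 - f3) / pmax(f0, 1e-12)), 0.003)
})
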