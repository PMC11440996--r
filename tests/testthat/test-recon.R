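test_that("gaussian smoothing is normalized, self-adjoint, and exact for a delta", {
  g <- imageGrid(c(15, 15, 15), c(2, 2.5, 3))
  img <- array(0, gridShape(g))
  img[8, 8, 8] <- 1
  expect_identical(gaussianSmooth(img, g, 0), img)
  sm <- gaussianSmooth(img, g, 6)
  # interior source: total mass conserved
  expect_lt(abs(sum(sm) - 1), 1e-6)
  # closed form: separable product of normalized discrete Gaussians
  ks <- lapply(1:3, function(a) {
    sig <- 6 / (2 * sqrt(2 * log(2))) / voxelSize(g)[a]
    r <- max(1, ceiling(4 * sig))
    k <- stats::dnorm((-r):r, 0, sig)
    k / sum(k)
  })
  pad <- function(k, n, c0) {
    out <- numeric(n)
    r <- (length(k) - 1) / 2
    for (j in -r:r) if (c0 + j >= 1 && c0 + j <= n) out[c0 + j] <- k[j + r + 1]
    out
  }
  closed <- outer(outer(pad(ks[[1]], 15, 8), pad(ks[[2]], 15, 8)),
                  pad(ks[[3]], 15, 8))
  expect_equal(sm, closed, tolerance = 1e-6)
  # self-adjointness
  set.seed(1)
  x <- array(runif(15^3), gridShape(g))
  y <- array(runif(15^3), gridShape(g))
  expect_lt(abs(sum(gaussianSmooth(x, g, 5) * y) -
                sum(x * gaussianSmooth(y, g, 5))) / abs(sum(x * y)), 1e-12)
})

test_that("single-voxel MLEM converges to the closed-form fixed point y/a", {
  g <- imageGrid(c(1, 1, 1), 2)
  rays <- raySet(matrix(c(-10, 0, 0), 1), matrix(c(10, 0, 0), 1))
  a <- forwardProject(array(1, c(1, 1, 1)), g, rays) # system weight
  sens <- backProject(1, rays, g)
  x <- array(1, c(1, 1, 1))
  y <- 3.7
  for (i in 1:5) x <- osemUpdate(x, y, rays, g, sens)
  expect_equal(as.numeric(x), y / as.numeric(a), tolerance = 1e-12)
})

test_that("consistent data leave the image fixed under a full MLEM update", {
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner; g <- cfg$grid
  sp <- sinogramSpec(15, 16, 3)
  x <- rasterizePhantom(phantomSpec(30, 36, 1), g) + 0.5 # strictly positive
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  y <- array(forwardProject(x, g, rays), c(15, 16, nPlanes(sp, sc)))
  r <- osemSino(y, sc, sp, g, 1, 1, init = x)
  expect_lt(max(abs(r$image - x) / x), 1e-10)
  # with a resolution model in the loop
  y2 <- array(forwardProject(gaussianSmooth(x, g, 5), g, rays), dim(y))
  r2 <- osemSino(y2, sc, sp, g, 1, 1, resFwhmMm = 5, init = x)
  expect_lt(max(abs(r2$image - x) / x), 1e-10)
})

test_that("MLEM increases the Poisson log-likelihood monotonically", {
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner; g <- cfg$grid
  sp <- sinogramSpec(15, 16, 3)
  x <- rasterizePhantom(phantomSpec(30, 36, 1), g)
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  lam <- array(forwardProject(x, g, rays), c(15, 16, nPlanes(sp, sc)))
  set.seed(7)
  yn <- array(stats::rpois(length(lam), lam * 3), dim(lam))
  r <- osemSino(yn, sc, sp, g, 20, 1, logLik = TRUE)
  ll <- r$log$logLik
  expect_length(ll, 20)
  expect_true(all(diff(ll) > -1e-8 * abs(ll[-1])))
  expect_gt(ll[20], ll[1])
})

test_that("OSEM recovers a noiseless uniform cylinder within 2%", {
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner; g <- cfg$grid
  sp <- sinogramSpec(15, 16, 3)
  truth <- rasterizePhantom(phantomSpec(30, 36, 1), g)
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  y <- array(forwardProject(truth, g, rays), c(15, 16, nPlanes(sp, sc)))
  r <- osemSino(y, sc, sp, g, 6, 8)
  rad <- sqrt(outer(axisCoords(g, 1)^2, axisCoords(g, 2)^2, "+"))
  inner <- array(FALSE, gridShape(g))
  for (k in which(abs(axisCoords(g, 3)) <= 12)) inner[, , k] <- rad <= 22
  expect_lt(abs(mean(r$image[inner]) - 1), 0.02)
  # non-negativity and zero-iteration behavior
  expect_true(all(r$image >= 0))
  r0 <- osemSino(y, sc, sp, g, 0, 8, init = truth + 1)
  expect_identical(r0$image, truth + 1)
  expect_error(osemSino(-y, sc, sp, g, 1, 1), "negative")
})

test_that("counts are conserved by MLEM on synthetic data", {
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner; g <- cfg$grid
  sp <- sinogramSpec(15, 16, 3)
  truth <- rasterizePhantom(phantomSpec(30, 36, 1), g)
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  lam <- array(forwardProject(truth, g, rays), c(15, 16, nPlanes(sp, sc)))
  set.seed(12)
  y <- array(stats::rpois(length(lam), lam), dim(lam))
  r <- osemSino(y, sc, sp, g, 10, 1)
  tot <- sum(forwardProject(r$image, g, rays))
  expect_lt(abs(tot - sum(y)) / sum(y), 0.005)
})

test_that("listmode and sinogram OSEM agree at convergence on the same data", {
  # overdetermined toy system (3840 LORs, 845 voxels) with enough counts
  # that integer data are nearly consistent with the generating image
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner
  sp <- sinogramSpec(15, 16, 3)
  g <- imageGrid(c(13, 13, 5), c(6, 6, 7))
  truth <- rasterizePhantom(phantomSpec(28, 30, 1), g)
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  lam <- array(forwardProject(truth, g, rays), c(15, 16, nPlanes(sp, sc)))
  y <- array(round(lam * 1e6 / sum(lam)), dim(lam))
  ev <- sinogramToEvents(y, sp, sc)
  set.seed(3)
  ev <- ev[sample.int(nrow(ev)), ]
  rs <- osemSino(y, sc, sp, g, 25, 4)
  rl <- osemLm(ev, sc, sp, g, 25, 4)
  rad <- sqrt(outer(axisCoords(g, 1)^2, axisCoords(g, 2)^2, "+"))
  fov <- array(FALSE, gridShape(g))
  for (k in 1:5) fov[, , k] <- rad <= 36
  rms <- sqrt(mean((rs$image[fov] - rl$image[fov])^2)) / mean(rs$image[truth > 0])
  expect_lt(rms, 0.01)
})

test_that("subset visiting order does not matter at convergence on noiseless data", {
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner; g <- cfg$grid
  sp <- sinogramSpec(15, 16, 3)
  truth <- rasterizePhantom(phantomSpec(30, 36, 1), g)
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  y <- array(forwardProject(truth, g, rays), c(15, 16, nPlanes(sp, sc)))
  r1 <- osemSino(y, sc, sp, g, 20, 4)
  r2 <- osemSino(y, sc, sp, g, 20, 4, subsetOrder = c(3, 1, 0, 2))
  m <- mean(r1$image[truth > 0])
  expect_lt(sqrt(mean((r1$image - r2$image)^2)) / m, 0.01)
})

test_that("sensitivity images are positive inside the FOV and subset-shared", {
  cfg <- presetConfig("toy-32crystal")
  sc <- cfg$scanner; g <- cfg$grid
  sp <- sinogramSpec(15, 16, 3)
  sens <- sensitivityImageLm(sc, sp, g)
  rad <- sqrt(outer(axisCoords(g, 1)^2, axisCoords(g, 2)^2, "+"))
  fov <- array(FALSE, gridShape(g))
  for (k in 2:6) fov[, , k] <- rad <= 30
  expect_true(all(sens[fov] > 0))
  # coarsened enumeration approximates the full one in total sensitivity
  sens2 <- sensitivityImageLm(sc, sp, g, viewStride = 2L)
  expect_true(all(sens2[fov] > 0))
  expect_lt(abs(sum(sens2[fov]) - sum(sens[fov])) / sum(sens[fov]), 0.05)
  # a single central LOR's sensitivity is its smoothed back projection
  r1 <- sinoIndexToRay(sp, sc, cbind(7L, 0L, 0L))
  s1 <- sensitivityImageSino(scannerModel(1, 2, 8, 60, 10),
                             sinogramSpec(15, 8, 0), g, views = 0L,
                             resFwhmMm = 4)
  expect_true(all(s1 >= 0))
  expect_error(sensitivityImageSino(sc, sp, g, views = integer(0)), "empty")
})
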