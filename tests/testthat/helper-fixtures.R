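# Shared fixtures and independent oracles for the test suite.

toyScanner <- function() scannerModel(4, 4, 8, 60, 10)

toySpec <- function(tof = NULL) sinogramSpec(15, 16, 3, tof = tof)

toyTof <- function() tofSpec(11, 20, 12)

# rays with endpoints on a sphere of the given radius (detector-like: both
# endpoints outside the volume), reproducible
sphereRays <- function(n, radius = 40, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(3 * n), n)
  a <- a / sqrt(rowSums(a^2)) * radius
  b <- matrix(rnorm(3 * n), n)
  b <- b / sqrt(rowSums(b^2)) * radius
  # avoid near-degenerate chords
  short <- sqrt(rowSums((a - b)^2)) < radius / 2
  b[short, ] <- -a[short, ]
  raySet(a, b)
}

# rays biased toward principal axis `axis`
axisRays <- function(n, axis, radius = 40, seed = 1) {
  set.seed(seed + axis)
  dirs <- matrix(rnorm(3 * n, sd = 0.2), n)
  dirs[, axis] <- sign(dirs[, axis]) + dirs[, axis]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  off <- matrix(runif(3 * n, -8, 8), n)
  off[, axis] <- 0
  raySet(off - dirs * radius, off + dirs * radius)
}

# smooth positive test image (random field blurred in-place)
smoothImage <- function(grid, seed = 1, fwhm = 6) {
  set.seed(seed)
  img <- array(runif(prod(gridShape(grid))), gridShape(grid))
  gaussianSmooth(img, grid, fwhm) + 0.05
}

# dense matrix oracle: build the forward operator column by column by
# projecting unit-voxel images (brute force; independent of any adjoint code)
denseForwardMatrix <- function(grid, rays, tof = NULL) {
  nv <- prod(gridShape(grid))
  ncols <- if (is.null(tof)) numRays(rays) * 1L else numRays(rays) * numBins(tof)
  A <- matrix(0, ncols, nv)
  for (j in seq_len(nv)) {
    e <- numeric(nv)
    e[j] <- 1
    e <- array(e, gridShape(grid))
    A[, j] <- if (is.null(tof)) forwardProject(e, grid, rays)
              else as.vector(forwardProjectTOF(e, grid, rays, tof))
  }
  A
}

# zero-padded trilinear interpolation of image at world points (n x 3)
trilinear <- function(points, image, grid) {
  f <- sweep(sweep(points, 2, gridOrigin(grid)), 2, voxelSize(grid), "/")
  i0 <- floor(f)
  w <- f - i0
  out <- numeric(nrow(points))
  sh <- gridShape(grid)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    iv <- i0 + matrix(rep(c(a, b, cc), each = nrow(points)), ncol = 3)
    wt <- (if (a) w[, 1] else 1 - w[, 1]) *
          (if (b) w[, 2] else 1 - w[, 2]) *
          (if (cc) w[, 3] else 1 - w[, 3])
    ok <- iv[, 1] >= 0 & iv[, 1] < sh[1] & iv[, 2] >= 0 & iv[, 2] < sh[2] &
          iv[, 3] >= 0 & iv[, 3] < sh[3]
    if (any(ok)) {
      lin <- iv[ok, 1] + sh[1] * (iv[ok, 2] + sh[2] * iv[ok, 3]) + 1
      out[ok] <- out[ok] + wt[ok] * image[lin]
    }
  }
  out
}

# fine-step midpoint quadrature of the trilinearly interpolated image along
# a segment; independent of the plane-stepping projector
quadLineIntegral <- function(image, grid, s, e, step = 0.01) {
  L <- sqrt(sum((e - s)^2))
  n <- ceiling(L / step)
  t <- (seq_len(n) - 0.5) * (L / n)
  u <- (e - s) / L
  pts <- cbind(s[1] + t * u[1], s[2] + t * u[2], s[3] + t * u[3])
  sum(trilinear(pts, image, grid)) * (L / n)
}

# chi-square statistic against given expectations, pooling cells with
# expectation < 5 into one cell; returns the p-value
chisqPooledP <- function(obs, expd) {
  keep <- expd >= 5
  X2 <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  df <- sum(keep) - 1L
  eP <- sum(expd[!keep])
  if (eP > 0) {
    X2 <- X2 + (sum(obs[!keep]) - eP)^2 / eP
    df <- df + 1L
  }
  stats::pchisq(X2, df, lower.tail = FALSE)
}

relErr <- function(a, b) {
  abs(a - b) / (abs(b) + 1e-12)
}
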