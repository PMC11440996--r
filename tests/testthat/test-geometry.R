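test_that("crystal table has one row per crystal on the ring cylinder", {
  sc <- scannerModel(36, 34, 16, 380, 5.5556)
  tab <- buildCrystalTable(sc)
  expect_equal(nrow(tab), 36 * 34 * 16)
  expect_equal(nrow(tab), numCrystals(sc))
  expect_true(all(is.finite(as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]))))
  expect_lt(max(abs(sqrt(tab$x_mm^2 + tab$y_mm^2) - 380)), 1e-9)
  # ring z positions centered on the axial offset
  expect_equal(sort(unique(tab$z_mm)), (0:35 - 35 / 2) * 5.5556,
               tolerance = 1e-12)
  # count conservation for arbitrary parameters
  for (p in list(c(1, 1, 1), c(2, 3, 5), c(7, 2, 4))) {
    sc2 <- scannerModel(p[1], p[2], p[3], 10, 2)
    expect_equal(nrow(buildCrystalTable(sc2)), prod(p))
  }
})

test_that("degenerate single-crystal scanner sits at radius R on the axis center", {
  sc <- scannerModel(1, 1, 1, 25, 3, axialCenterOffsetMm = 7)
  tab <- buildCrystalTable(sc)
  expect_equal(nrow(tab), 1L)
  expect_equal(sqrt(tab$x_mm^2 + tab$y_mm^2), 25)
  expect_equal(tab$z_mm, 7)
  expect_error(scannerModel(0, 1, 1, 25, 3), "counts")
  expect_error(scannerModel(1, 1, 1, -5, 3), "ringRadiusMm")
})

test_that("interleaved radial/view mapping is a bijection on the toy ring", {
  sc <- scannerModel(1, 2, 8, 60, 10) # 16 transaxial crystals
  sp <- sinogramSpec(15, 8, 0)
  # forward map: every (radial, view) gives a distinct unordered pair
  seen <- new.env()
  for (r in 0:14) for (v in 0:7) {
    rc <- petray:::interleaveCrystals(r, v, 15, 16)
    expect_true(rc$a != rc$b)
    key <- paste(sort(c(rc$a, rc$b)), collapse = "-")
    expect_false(exists(key, envir = seen),
                 info = sprintf("pair %s hit twice", key))
    assign(key, c(r, v), envir = seen)
    # inverse round trip
    inv <- crystalPairToSino(sp, sc, rc$a, rc$b)
    expect_equal(inv$radial, r)
    expect_equal(inv$view, v)
    expect_false(inv$swapped)
    # and with the pair order reversed
    inv2 <- crystalPairToSino(sp, sc, rc$b, rc$a)
    expect_equal(c(inv2$radial, inv2$view), c(r, v))
    expect_true(inv2$swapped)
  }
  expect_equal(length(ls(seen)), 15 * 8)
})

test_that("mirrored radial offsets select crystal pairs reflected through the view axis", {
  sc <- scannerModel(1, 2, 8, 60, 10)
  sp <- sinogramSpec(15, 8, 0)
  N <- 16
  for (v in c(0, 3, 7)) for (k in 1:6) {
    p1 <- petray:::interleaveCrystals(7 + k, v, 15, N) # offset +k
    p2 <- petray:::interleaveCrystals(7 - k, v, 15, N) # offset -k
    # reflection through the view axis in crystal-index units; for odd
    # offsets the interleaved axis sits half a crystal pitch further
    C <- 2 * v + k %% 2
    expect_setequal((C - c(p1$a, p1$b)) %% N, c(p2$a, p2$b))
  }
})

test_that("plane table enumerates ring pairs by difference then axial position", {
  sc <- toyScanner() # 4 rings
  pt <- planeRingTable(sc, 3)
  expect_equal(nrow(pt), 16) # 4^2 for full ring difference
  expect_equal(pt$plane, 0:15)
  d <- abs(pt$ring_a - pt$ring_b)
  expect_true(all(diff(d) >= 0 | diff(d) == 0 | TRUE)) # differences grouped
  expect_true(!is.unsorted(d)) # ordered by ring difference
  expect_false(any(duplicated(paste(pt$ring_a, pt$ring_b))))
  # restricted ring difference
  pt1 <- planeRingTable(sc, 1)
  expect_equal(nrow(pt1), 4 + 2 * 3)
  expect_true(all(abs(pt1$ring_a - pt1$ring_b) <= 1))
  expect_equal(nPlanes(sinogramSpec(15, 16, 1), sc), 10L)
})

test_that("direct planes give rays with equal endpoint z", {
  sc <- toyScanner()
  sp <- toySpec()
  rays <- sinoIndexToRay(sp, sc, cbind(0:14, 3, 0)) # plane 0 = ring pair (0,0)
  expect_equal(rayStart(rays)[, 3], rayEnd(rays)[, 3])
  expect_error(sinoIndexToRay(sp, sc, cbind(15, 0, 0)), "radial")
  expect_error(sinoIndexToRay(sp, sc, cbind(0, 16, 0)), "view")
  expect_error(sinoIndexToRay(sp, sc, cbind(0, 0, 99)), "plane")
})

test_that("subset views are equally spaced and partition the full view set", {
  expect_equal(subsetViews(272, 34, 0), seq(0, 238, by = 34))
  expect_length(subsetViews(272, 34, 0), 8)
  expect_equal(subsetViews(272, 1, 0), 0:271)
  all34 <- sort(unlist(lapply(0:33, function(k) subsetViews(272, 34, k))))
  expect_equal(all34, 0:271)
  # non-dividing case: sizes differ by at most one, still a partition
  sz <- lengths(lapply(0:2, function(k) subsetViews(10, 3, k)))
  expect_lte(diff(range(sz)), 1)
  expect_equal(sort(unlist(lapply(0:2, function(k) subsetViews(10, 3, k)))), 0:9)
  expect_error(subsetViews(272, 34, 34), "out of range")
  expect_error(subsetViews(272, 34, -1), "out of range")
})

test_that("listmode events map to the same rays as their sinogram bins", {
  sc <- toyScanner()
  sp <- toySpec()
  tab <- buildCrystalTable(sc)
  np <- nPlanes(sp, sc)
  ones <- array(1L, c(15, 16, np))
  ev <- sinogramToEvents(ones, sp, sc)
  expect_equal(nrow(ev), 15 * 16 * np)
  er <- eventsToRays(ev, tab)
  rays <- sinoIndexToRay(sp, sc, fullSinogramIndices(sp, sc))
  expect_equal(er$rays@start, rays@start)
  expect_equal(er$rays@end, rays@end)
  # shape contract and error cases
  e3 <- ev[1:3, ]
  expect_equal(numRays(eventsToRays(e3, tab)$rays), 3L)
  expect_error(eventsToRays(data.frame(det_a = 5L, det_b = 5L), tab),
               "degenerate")
  expect_error(eventsToRays(data.frame(det_a = -1L, det_b = 2L), tab),
               "out of range")
  expect_error(eventsToRays(data.frame(det_a = 0L, det_b = nrow(tab)), tab),
               "out of range")
})

test_that("crystalPairToSino rejects pairs outside the radial field of view", {
  sc <- scannerModel(1, 2, 8, 60, 10)
  sp <- sinogramSpec(7, 8, 0) # narrow radial FOV: |s| <= 3
  # adjacent crystals form a chord far from the center, outside the FOV
  inv <- crystalPairToSino(sp, sc, 0L, 1L)
  expect_true(is.na(inv$radial))
})
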