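# Scanner geometry: crystal coordinates, sinogram indexing, subsets, events.

#' Build the crystal coordinate table of a cylindrical scanner
#'
#' One row per crystal, ordered by global id \code{ring * nTransaxial +
#' transaxial} (0-based).  The transaxial angle of crystal t is
#' \code{2*pi*t/N + angularOffset} when module gaps are zero; with a gap,
#' crystals stay equally spaced within a module and modules are separated by
#' the gap.  Ring r sits at \code{axialCenterOffsetMm + (r - (nRings-1)/2) *
#' axialPitchMm}.
#'
#' @param scanner a \linkS4class{ScannerModel}.
#' @return A data.frame with columns \code{crystal_id}, \code{ring},
#'   \code{transaxial}, \code{x_mm}, \code{y_mm}, \code{z_mm}.
#' @examples
#' tab <- buildCrystalTable(scannerModel(36, 34, 16, 380, 5.56))
#' nrow(tab)  # 19584
#' @export
buildCrystalTable <- function(scanner) {
  stopifnot(is(scanner, "ScannerModel"))
  nt <- numTransaxial(scanner)
  nr <- scanner@nRings
  t <- 0:(nt - 1L)
  if (scanner@moduleGapRad > 0) {
    m <- scanner@modulesPerRing
    cpm <- scanner@crystalsPerModule
    dAng <- (2 * pi - m * scanner@moduleGapRad) / nt
    mod <- t %/% cpm
    within <- t %% cpm
    ang <- scanner@angularOffset + mod * (cpm * dAng + scanner@moduleGapRad) +
      within * dAng
  } else {
    ang <- scanner@angularOffset + 2 * pi * t / nt
  }
  x <- scanner@ringRadiusMm * cos(ang)
  y <- scanner@ringRadiusMm * sin(ang)
  ring <- rep(0:(nr - 1L), each = nt)
  z <- scanner@axialCenterOffsetMm +
    (ring - (nr - 1L) / 2) * scanner@axialPitchMm
  data.frame(
    crystal_id = ring * nt + rep(t, nr),
    ring = ring,
    transaxial = rep(t, nr),
    x_mm = rep(x, nr),
    y_mm = rep(y, nr),
    z_mm = z
  )
}

#' Plane number to ring-pair table for a span-1 sinogram
#'
#' Planes enumerate all (ring_a, ring_b) pairs with
#' \code{|ring_a - ring_b| <= maxRingDiff}: first the direct planes
#' (difference 0) in axial order, then for each difference d = 1, 2, ... the
#' pairs with \code{ring_b - ring_a = +d} followed by those with \code{-d},
#' each in axial order.  For maxRingDiff = nRings - 1 this yields nRings^2
#' planes.
#'
#' @param scanner a \linkS4class{ScannerModel}.
#' @param maxRingDiff maximum ring difference.
#' @return data.frame with 0-based columns \code{plane}, \code{ring_a},
#'   \code{ring_b}.
#' @export
planeRingTable <- function(scanner, maxRingDiff) {
  n <- scanner@nRings
  mrd <- min(as.integer(maxRingDiff), n - 1L)
  ra <- 0:(n - 1L)
  rb <- ra
  for (d in seq_len(mrd)) {
    a <- 0:(n - 1L - d)
    ra <- c(ra, a, a + d)
    rb <- c(rb, a + d, a)
  }
  data.frame(plane = seq_along(ra) - 1L, ring_a = ra, ring_b = rb)
}

# Standard interleaved transaxial mapping: view v in [0, N/2), signed radial
# offset s; s = radial - (nRadial-1)/2.
interleaveCrystals <- function(radial, view, nRadial, nTrans) {
  s <- radial - (nRadial - 1L) / 2
  a <- (view + floor((s + 1) / 2)) %% nTrans
  b <- (view - floor(s / 2) + nTrans / 2) %% nTrans
  list(a = as.integer(a), b = as.integer(b))
}

#' Map sinogram indices to world-coordinate rays
#'
#' Converts (radial, view, plane) sinogram indices (0-based) to the
#' start/end world coordinates of the two crystals forming each bin, using
#' the standard interleaved transaxial convention -- for N transaxial
#' crystals, view v and signed radial offset s = radial - (nRadial-1)/2:
#' crystal_a = (v + floor((s+1)/2)) mod N, crystal_b = (v - floor(s/2) + N/2)
#' mod N -- and the span-1 plane table of [planeRingTable()].  The ray start
#' is crystal (ring_a, crystal_a), the end crystal (ring_b, crystal_b).
#'
#' @param spec a \linkS4class{SinogramSpec}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @param indices N x 3 matrix (or data.frame) of 0-based (radial, view,
#'   plane) indices.
#' @param table optional precomputed [buildCrystalTable()] output.
#' @param planes optional precomputed [planeRingTable()] output.
#' @return A \linkS4class{RaySet}.
#' @export
sinoIndexToRay <- function(spec, scanner, indices, table = NULL, planes = NULL) {
  stopifnot(is(spec, "SinogramSpec"), is(scanner, "ScannerModel"))
  indices <- as.matrix(indices)
  if (ncol(indices) != 3L) stop("indices must have 3 columns (radial, view, plane)")
  if (is.null(table)) table <- buildCrystalTable(scanner)
  if (is.null(planes)) planes <- planeRingTable(scanner, spec@maxRingDiff)
  radial <- as.integer(indices[, 1]); view <- as.integer(indices[, 2])
  plane <- as.integer(indices[, 3])
  if (any(radial < 0L | radial >= spec@nRadial))
    stop("radial index out of range")
  if (any(view < 0L | view >= spec@nViews))
    stop("view index out of range")
  if (any(plane < 0L | plane >= nrow(planes)))
    stop("plane index out of range")
  nt <- numTransaxial(scanner)
  tc <- interleaveCrystals(radial, view, spec@nRadial, nt)
  ra <- planes$ring_a[plane + 1L]
  rb <- planes$ring_b[plane + 1L]
  ia <- ra * nt + tc$a + 1L # table row (table is ordered by crystal_id)
  ib <- rb * nt + tc$b + 1L
  raySet(
    cbind(table$x_mm[ia], table$y_mm[ia], table$z_mm[ia]),
    cbind(table$x_mm[ib], table$y_mm[ib], table$z_mm[ib])
  )
}

#' Invert the sinogram indexing: crystal pair to (radial, view, plane)
#'
#' Maps per-event crystal pairs (global 0-based ids) back to 0-based
#' (radial, view, plane) indices, the inverse of [sinoIndexToRay()] on its
#' image.  Pairs outside the radial field of view or beyond the maximum ring
#' difference yield NA.  \code{swapped} records whether the (a, b) order of
#' the matching sinogram bin is the reverse of the input order (relevant for
#' the TOF bin sign).
#'
#' @param spec a \linkS4class{SinogramSpec}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @param detA,detB integer vectors of global crystal ids (0-based).
#' @return data.frame with columns \code{radial}, \code{view}, \code{plane},
#'   \code{swapped}.
#' @export
crystalPairToSino <- function(spec, scanner, detA, detB) {
  nt <- numTransaxial(scanner)
  nr <- spec@nRadial
  half <- (nr - 1L) / 2
  planes <- planeRingTable(scanner, spec@maxRingDiff)
  planeOf <- matrix(NA_integer_, scanner@nRings, scanner@nRings)
  planeOf[cbind(planes$ring_a + 1L, planes$ring_b + 1L)] <- planes$plane

  solveOne <- function(ta, tb) {
    # try the (ta, tb) ordering of the interleave formulas
    sp <- (ta - tb + nt / 2) %% nt
    s <- if (sp > nt / 2) sp - nt else sp
    v <- (ta - floor((s + 1) / 2)) %% nt
    r <- s + half
    if (v >= 0 && v < spec@nViews && r >= 0 && r < nr) {
      chk <- interleaveCrystals(r, v, nr, nt)
      if (chk$a == ta && chk$b == tb) return(c(r, v))
    }
    c(NA_integer_, NA_integer_)
  }

  n <- length(detA)
  radial <- view <- plane <- rep(NA_integer_, n)
  swapped <- rep(NA, n)
  ringA <- detA %/% nt; transA <- detA %% nt
  ringB <- detB %/% nt; transB <- detB %% nt
  for (i in seq_len(n)) {
    rv <- solveOne(transA[i], transB[i])
    sw <- FALSE
    ra <- ringA[i]; rb <- ringB[i]
    if (is.na(rv[1])) {
      rv <- solveOne(transB[i], transA[i])
      sw <- TRUE
      ra <- ringB[i]; rb <- ringA[i]
    }
    if (is.na(rv[1])) next
    p <- planeOf[ra + 1L, rb + 1L]
    if (is.na(p)) next
    radial[i] <- rv[1]; view[i] <- rv[2]; plane[i] <- p; swapped[i] <- sw
  }
  data.frame(radial = radial, view = view, plane = plane, swapped = swapped)
}

#' Views belonging to an OSEM subset
#'
#' Equally spaced view subsets: subset k of n contains views
#' \code{k, k + n, k + 2n, ...}.  When nSubsets does not divide nViews the
#' subset sizes differ by at most one.
#'
#' @param nViews total number of views.
#' @param nSubsets number of subsets.
#' @param k 0-based subset index.
#' @return Integer vector of 0-based view indices.
#' @examples
#' subsetViews(272, 34, 0)  # 8 views: 0, 34, ..., 238
#' @export
subsetViews <- function(nViews, nSubsets, k) {
  nViews <- as.integer(nViews); nSubsets <- as.integer(nSubsets)
  if (nSubsets < 1L || nSubsets > nViews)
    stop("nSubsets must be between 1 and nViews")
  if (k < 0L || k >= nSubsets) stop("subset index k out of range")
  seq.int(from = k, to = nViews - 1L, by = nSubsets)
}

#' Convert listmode events to rays
#'
#' Looks up the world coordinates of each event's crystal pair: the ray
#' start is the first crystal (\code{det_a}), the end the second
#' (\code{det_b}); the signed TOF bin is positive toward the end point.
#' Events with identical crystals are rejected (zero-length ray).
#'
#' @param events data.frame with 0-based global crystal id columns
#'   \code{det_a}, \code{det_b} and optionally a signed \code{tof_bin}.
#' @param table a [buildCrystalTable()] data.frame.
#' @return list with \code{rays} (a \linkS4class{RaySet}) and \code{tofBin}
#'   (integer vector, zeros when absent), in event order.
#' @export
eventsToRays <- function(events, table) {
  a <- as.integer(events$det_a)
  b <- as.integer(events$det_b)
  nc <- nrow(table)
  if (any(a < 0L | a >= nc) || any(b < 0L | b >= nc))
    stop("crystal index out of range")
  if (any(a == b))
    stop("degenerate ray: event with identical crystals")
  tofBin <- if (!is.null(events$tof_bin)) as.integer(events$tof_bin)
            else integer(length(a))
  # table rows are ordered by crystal_id
  list(
    rays = raySet(
      cbind(table$x_mm[a + 1L], table$y_mm[a + 1L], table$z_mm[a + 1L]),
      cbind(table$x_mm[b + 1L], table$y_mm[b + 1L], table$z_mm[b + 1L])
    ),
    tofBin = tofBin
  )
}

#' All (radial, view, plane) indices of a sinogram, in canonical order
#'
#' Canonical "PVR" flattening: radial fastest, then view, then plane,
#' matching \code{as.vector()} on an array of dim (nRadial, nViews, nPlanes).
#'
#' @param spec a \linkS4class{SinogramSpec}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @param views optional subset of 0-based view indices (default: all).
#' @return N x 3 integer matrix of 0-based (radial, view, plane) indices.
#' @export
fullSinogramIndices <- function(spec, scanner, views = NULL) {
  if (is.null(views)) views <- 0:(spec@nViews - 1L)
  np <- nPlanes(spec, scanner)
  g <- expand.grid(radial = 0:(spec@nRadial - 1L), view = as.integer(views),
                   plane = 0:(np - 1L))
  as.matrix(g)
}

#' Expand an integer sinogram into a listmode event table
#'
#' Each count in bin (radial, view, plane [, TOF bin]) becomes one event
#' carrying the bin's crystal pair and signed TOF bin.  Used by the
#' simulator and to construct exactly equivalent listmode/sinogram data
#' pairs.
#'
#' @param counts integer array of dim (nRadial, nViews, nPlanes) or
#'   (nRadial, nViews, nPlanes, nBins) in canonical order.
#' @param spec a \linkS4class{SinogramSpec}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @return data.frame with columns \code{det_a}, \code{det_b},
#'   \code{tof_bin} (signed; 0 without TOF).
#' @export
sinogramToEvents <- function(counts, spec, scanner) {
  d <- dim(counts)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("counts must be a 3D or 4D array")
  np <- nPlanes(spec, scanner)
  if (d[1] != spec@nRadial || d[2] != spec@nViews || d[3] != np)
    stop("counts dimensions do not match the sinogram spec")
  cnt <- as.vector(counts)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  nz <- which(cnt > 0)
  if (length(nz) == 0L)
    return(data.frame(det_a = integer(0), det_b = integer(0),
                      tof_bin = integer(0)))
  idx <- rep(nz, cnt[nz]) - 1L # 0-based flat indices
  nR <- d[1]; nV <- d[2]
  radial <- idx %% nR
  view <- (idx %/% nR) %% nV
  plane <- (idx %/% (nR * nV)) %% np
  tof_bin <- if (length(d) == 4L) {
    hb <- (d[4] - 1L) %/% 2L
    as.integer(idx %/% (nR * nV * np)) - hb
  } else integer(length(idx))
  nt <- numTransaxial(scanner)
  tc <- interleaveCrystals(radial, view, spec@nRadial, nt)
  planes <- planeRingTable(scanner, spec@maxRingDiff)
  ra <- planes$ring_a[plane + 1L]
  rb <- planes$ring_b[plane + 1L]
  data.frame(det_a = ra * nt + tc$a, det_b = rb * nt + tc$b,
             tof_bin = as.integer(tof_bin))
}
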