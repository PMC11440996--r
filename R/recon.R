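# MLEM / OSEM reconstruction, sinogram and listmode, with an image-based
# Gaussian resolution model.  Forward model: ybar = M P G x + s with G a
# shift-invariant Gaussian convolution, P the Joseph projector (non-TOF or
# TOF), M diagonal multiplicative factors (attenuation/normalization enter
# only here) and s an additive contamination term.

#' Separable Gaussian smoothing (image-based resolution model)
#'
#' Convolves the image with a 3D isotropic Gaussian of the given FWHM (mm),
#' applied separably per axis with the per-axis sigma \code{fwhm / (2
#' sqrt(2 log 2)) / voxel}.  The discrete kernel is truncated at 4 sigma and
#' normalized to unit sum; boundaries are zero-padded, so the operator is
#' exactly self-adjoint and conserves the total sum for interior sources
#' (mass leaks only through the image border).  \code{fwhmMm = 0} is the
#' identity.
#'
#' @param image 3D array on \code{grid}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param fwhmMm isotropic FWHM in mm, >= 0.
#' @return Smoothed 3D array.
#' @export
gaussianSmooth <- function(image, grid, fwhmMm) {
  stopifnot(is(grid, "ImageGrid"), fwhmMm >= 0)
  image <- checkImage(image, grid)
  if (fwhmMm == 0) return(image)
  for (axis in 1:3) {
    sig <- sigmaFromFwhm(fwhmMm) / grid@voxelSize[axis]
    if (sig < 1e-6) next
    r <- max(1L, ceiling(4 * sig))
    k <- exp(-((-r):r)^2 / (2 * sig^2))
    k <- k / sum(k)
    n <- grid@shape[axis]
    K <- matrix(0, n, n)
    for (j in (-r):r) {
      i <- seq_len(n)
      ok <- i + j >= 1L & i + j <= n
      K[cbind(i[ok] + j, i[ok])] <- k[j + r + 1L]
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- K %*% matrix(aperm(image, perm), nrow = n)
    image <- aperm(array(m, dim = grid@shape[perm]), order(perm))
  }
  image
}

#' Sinogram-mode sensitivity image of one OSEM subset
#'
#' The back projection, through the full forward model adjoint, of the
#' multiplicative factors (ones by default) over the subset's LORs:
#' \eqn{G^T P^T M^T 1}.  With a TOF spec all TOF bins contribute.
#'
#' @param scanner a \linkS4class{ScannerModel}.
#' @param spec a \linkS4class{SinogramSpec}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param views 0-based view indices of the subset (see [subsetViews()]).
#' @param resFwhmMm resolution-model FWHM in mm (0 disables).
#' @param mult optional per-LOR multiplicative factors for the subset
#'   (vector, or N x nBins matrix in TOF mode), default 1.
#' @param table,planes optional precomputed geometry tables.
#' @return 3D sensitivity image.
#' @export
sensitivityImageSino <- function(scanner, spec, grid, views, resFwhmMm = 0,
                                 mult = NULL, table = NULL, planes = NULL) {
  if (length(views) == 0L) stop("empty subset")
  idx <- fullSinogramIndices(spec, scanner, views)
  rays <- sinoIndexToRay(spec, scanner, idx, table = table, planes = planes)
  img <- if (!is.null(spec@tof)) {
    v <- if (is.null(mult)) matrix(1, numRays(rays), spec@tof@nBins) else mult
    backProjectTOF(v, rays, grid, spec@tof)
  } else {
    v <- if (is.null(mult)) rep(1, numRays(rays)) else mult
    backProject(v, rays, grid)
  }
  gaussianSmooth(img, grid, resFwhmMm)
}

#' Listmode-mode sensitivity image
#'
#' The standard listmode-OSEM sensitivity: the non-TOF back projection of
#' the multiplicative factors over ALL LORs of the scanner (the TOF bins of
#' a LOR sum to its full sensitivity up to kernel truncation), smoothed by
#' the resolution model.  Divide by the subset count for per-subset use; all
#' listmode subsets share the same sensitivity.  \code{viewStride} coarsens
#' the LOR enumeration (every m-th view, rescaled by m) for desk-scale runs;
#' it is an approximation flag, exact only at 1.
#'
#' @inheritParams sensitivityImageSino
#' @param viewStride positive integer; every viewStride-th view is used and
#'   the result is multiplied by viewStride.
#' @param multLor optional per-LOR multiplicative factors over the
#'   (possibly coarsened) LOR set.
#' @return 3D sensitivity image for the whole scanner.
#' @export
sensitivityImageLm <- function(scanner, spec, grid, resFwhmMm = 0,
                               viewStride = 1L, multLor = NULL,
                               table = NULL, planes = NULL) {
  viewStride <- as.integer(viewStride)
  stopifnot(viewStride >= 1L)
  views <- seq.int(0L, spec@nViews - 1L, by = viewStride)
  idx <- fullSinogramIndices(spec, scanner, views)
  rays <- sinoIndexToRay(spec, scanner, idx, table = table, planes = planes)
  v <- if (is.null(multLor)) rep(1, numRays(rays)) else multLor
  img <- backProject(v, rays, grid) * viewStride
  gaussianSmooth(img, grid, resFwhmMm)
}

# Forward model application for one subset.  Returns the expectation ybar.
modelForward <- function(x, grid, rays, tof, tofBins, resFwhmMm, mult, add) {
  xs <- gaussianSmooth(x, grid, resFwhmMm)
  fp <- if (is.null(tof)) forwardProject(xs, grid, rays)
        else if (is.null(tofBins)) forwardProjectTOF(xs, grid, rays, tof)
        else forwardProjectTOFLm(xs, grid, rays, tofBins, tof)
  if (!is.null(mult)) fp <- mult * fp
  if (!is.null(add)) fp <- fp + add
  fp
}

# Adjoint of the forward model applied to per-LOR/per-event values.
modelAdjoint <- function(v, grid, rays, tof, tofBins, resFwhmMm, mult) {
  if (!is.null(mult)) v <- mult * v
  bp <- if (is.null(tof)) backProject(v, rays, grid)
        else if (is.null(tofBins)) backProjectTOF(v, rays, grid, tof)
        else backProjectTOFLm(v, rays, tofBins, grid, tof)
  gaussianSmooth(bp, grid, resFwhmMm)
}

#' One MLEM/OSEM multiplicative update
#'
#' \deqn{x' = \frac{x}{S_k} \, G^T P^T M^T \frac{y_k}{M P G x + s_k}}
#' In listmode mode \eqn{y_k} is 1 per event and the ratio is evaluated per
#' event.  Denominators are clamped at \code{epsFrac * median(ybar)}; voxels
#' where the sensitivity is not positive are left unchanged.  Bins/events
#' with \code{y = 0} contribute 0 to the ratio (the 0/0 limit).
#'
#' @param x current image (strictly positive where updated).
#' @param data subset data: vector (non-TOF sinogram), N x nBins matrix
#'   (TOF sinogram), or NULL in listmode mode (implicit ones).
#' @param rays subset \linkS4class{RaySet}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param sens subset sensitivity image (see [sensitivityImageSino()] /
#'   [sensitivityImageLm()]).
#' @param tof optional \linkS4class{TOFSpec}.
#' @param tofBins signed per-event TOF bins (listmode TOF mode only).
#' @param resFwhmMm resolution-model FWHM in mm.
#' @param mult,add optional multiplicative / additive model terms shaped
#'   like the data (or per event).
#' @param epsFrac denominator clamp as a fraction of median(ybar).
#' @return Updated image.
#' @export
osemUpdate <- function(x, data, rays, grid, sens, tof = NULL, tofBins = NULL,
                       resFwhmMm = 0, mult = NULL, add = NULL,
                       epsFrac = 1e-10) {
  listmode <- is.null(data)
  ybar <- modelForward(x, grid, rays, tof, tofBins, resFwhmMm, mult, add)
  eps <- max(epsFrac * stats::median(ybar), .Machine$double.xmin)
  if (listmode) {
    ratio <- 1 / pmax(ybar, eps)
  } else {
    if (any(data < 0)) stop("negative data")
    ratio <- ifelse(data == 0, 0, data / pmax(ybar, eps))
  }
  bp <- modelAdjoint(ratio, grid, rays, tof, tofBins, resFwhmMm, mult)
  ifelse(sens > 0, x * bp / ifelse(sens > 0, sens, 1), x)
}

#' OSEM reconstruction from a sinogram
#'
#' Ordered-subsets EM over equally spaced view subsets (MLEM when
#' \code{nSubsets = 1}), with the forward model \eqn{\bar y = M P G x + s}.
#' Deterministic given its inputs; subsets are visited in index order.
#'
#' @param y measured sinogram, dim (nRadial, nViews, nPlanes) or
#'   (nRadial, nViews, nPlanes, nBins) when \code{spec} carries a TOF spec;
#'   canonical "PVR" order (radial fastest).
#' @param scanner a \linkS4class{ScannerModel}.
#' @param spec a \linkS4class{SinogramSpec}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param nIterations full iterations (each visits every subset once); 0
#'   returns the initial image.
#' @param nSubsets number of view subsets.
#' @param resFwhmMm resolution-model FWHM in mm.
#' @param mult,add optional arrays shaped like \code{y}.
#' @param init initial image (default: uniform 1).
#' @param logLik if TRUE, record the full-data Poisson log-likelihood
#'   \eqn{\sum y \log\bar y - \bar y} after every subset update (costs one
#'   full forward projection per update).
#' @param epsFrac denominator clamp fraction.
#' @param subsetOrder optional permutation of \code{0:(nSubsets-1)} fixing
#'   the visiting order within each iteration (default: index order).
#' @return list with \code{image} and a per-update data.frame \code{log}
#'   (columns iteration, subset, logLik).
#' @export
osemSino <- function(y, scanner, spec, grid, nIterations, nSubsets,
                     resFwhmMm = 0, mult = NULL, add = NULL, init = NULL,
                     logLik = FALSE, epsFrac = 1e-10, subsetOrder = NULL) {
  np <- nPlanes(spec, scanner)
  tof <- spec@tof
  dExp <- c(spec@nRadial, spec@nViews, np, if (!is.null(tof)) tof@nBins)
  if (!identical(dim(y), as.integer(dExp)))
    stop("y dimensions do not match the sinogram spec")
  if (any(y < 0)) stop("negative data")
  table <- buildCrystalTable(scanner)
  planes <- planeRingTable(scanner, spec@maxRingDiff)

  sliceSub <- function(a, views) {
    if (is.null(a)) return(NULL)
    s <- if (is.null(tof)) a[, views + 1L, , drop = FALSE]
         else a[, views + 1L, , , drop = FALSE]
    if (is.null(tof)) as.vector(s) else matrix(as.vector(s), ncol = tof@nBins)
  }
  subs <- lapply(seq_len(nSubsets) - 1L, function(k) {
    views <- subsetViews(spec@nViews, nSubsets, k)
    rays <- sinoIndexToRay(spec, scanner,
                           fullSinogramIndices(spec, scanner, views),
                           table = table, planes = planes)
    mk <- sliceSub(mult, views)
    list(views = views, rays = rays, y = sliceSub(y, views), mult = mk,
         add = sliceSub(add, views),
         sens = sensitivityImageSino(scanner, spec, grid, views, resFwhmMm,
                                     mult = mk, table = table, planes = planes))
  })

  if (is.null(subsetOrder)) subsetOrder <- seq_len(nSubsets) - 1L
  if (!setequal(subsetOrder, seq_len(nSubsets) - 1L))
    stop("subsetOrder must be a permutation of 0:(nSubsets-1)")
  x <- if (is.null(init)) array(1, grid@shape) else checkImage(init, grid)
  if (any(x < 0)) stop("initial image must be non-negative")
  rec <- list()
  if (nIterations >= 1) for (it in seq_len(nIterations)) {
    for (k in subsetOrder + 1L) {
      s <- subs[[k]]
      x <- osemUpdate(x, s$y, s$rays, grid, s$sens, tof = tof,
                      resFwhmMm = resFwhmMm, mult = s$mult, add = s$add,
                      epsFrac = epsFrac)
      ll <- NA_real_
      if (logLik) {
        yb <- unlist(lapply(subs, function(s2)
          modelForward(x, grid, s2$rays, tof, NULL, resFwhmMm, s2$mult,
                       s2$add)))
        yv <- unlist(lapply(subs, function(s2) s2$y))
        ll <- sum(yv * log(pmax(yb, .Machine$double.xmin)) - yb)
      }
      rec[[length(rec) + 1L]] <- data.frame(iteration = it, subset = k - 1L,
                                            logLik = ll)
    }
  }
  list(image = x, log = do.call(rbind, c(rec, list(
    data.frame(iteration = integer(0), subset = integer(0),
               logLik = numeric(0))))))
}

#' OSEM reconstruction from listmode events
#'
#' Listmode ordered-subsets EM: subsets are event-index strides (event i
#' belongs to subset i mod nSubsets), the per-event "data" is 1, and the
#' sensitivity is the full-scanner non-TOF sensitivity divided by the subset
#' count (identical for all subsets).  TOF is used when \code{spec} carries
#' a TOF spec (per-event signed bins from \code{events$tof_bin}).
#'
#' @param events data.frame with columns \code{det_a}, \code{det_b} and,
#'   for TOF, signed \code{tof_bin}.
#' @inheritParams osemSino
#' @param multEvents,addEvents optional per-event model terms.
#' @param sens optional precomputed full-scanner sensitivity (before the
#'   division by nSubsets), e.g. from [sensitivityImageLm()].
#' @param viewStride coarsening stride for the sensitivity LOR enumeration.
#' @return list with \code{image} and per-update \code{log} (columns
#'   iteration, subset, logLik: the event term plus \eqn{-\langle
#'   \mathrm{sens}, x\rangle}, additive contamination total not included).
#' @export
osemLm <- function(events, scanner, spec, grid, nIterations, nSubsets,
                   resFwhmMm = 0, multEvents = NULL, addEvents = NULL,
                   init = NULL, sens = NULL, viewStride = 1L,
                   logLik = FALSE, epsFrac = 1e-10) {
  table <- buildCrystalTable(scanner)
  tof <- spec@tof
  er <- eventsToRays(events, table)
  nE <- numRays(er$rays)
  if (nE == 0L) stop("empty event list")
  if (is.null(sens))
    sens <- sensitivityImageLm(scanner, spec, grid, resFwhmMm, viewStride,
                               table = table)
  sensK <- sens / nSubsets

  subIdx <- lapply(seq_len(nSubsets) - 1L,
                   function(k) which((seq_len(nE) - 1L) %% nSubsets == k))
  if (any(lengths(subIdx) == 0L)) stop("empty subset")
  x <- if (is.null(init)) array(1, grid@shape) else checkImage(init, grid)
  rec <- list()
  if (nIterations >= 1) for (it in seq_len(nIterations)) {
    for (k in seq_len(nSubsets)) {
      i <- subIdx[[k]]
      rays <- raySet(er$rays@start[i, , drop = FALSE],
                     er$rays@end[i, , drop = FALSE])
      tb <- if (is.null(tof)) NULL else er$tofBin[i]
      x <- osemUpdate(x, NULL, rays, grid, sensK, tof = tof, tofBins = tb,
                      resFwhmMm = resFwhmMm,
                      mult = if (is.null(multEvents)) NULL else multEvents[i],
                      add = if (is.null(addEvents)) NULL else addEvents[i],
                      epsFrac = epsFrac)
      ll <- NA_real_
      if (logLik) {
        tbAll <- if (is.null(tof)) NULL else er$tofBin
        yb <- modelForward(x, grid, er$rays, tof, tbAll, resFwhmMm,
                           multEvents, addEvents)
        ll <- sum(log(pmax(yb, .Machine$double.xmin))) - sum(sens * x)
      }
      rec[[length(rec) + 1L]] <- data.frame(iteration = it, subset = k - 1L,
                                            logLik = ll)
    }
  }
  list(image = x, log = do.call(rbind, c(rec, list(
    data.frame(iteration = integer(0), subset = integer(0),
               logLik = numeric(0))))))
}
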