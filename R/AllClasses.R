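#' @useDynLib petray, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImageGrid

#' 3D voxel lattice with physical spacing and world placement
#'
#' An \code{ImageGrid} describes where a 3D image array lives in world
#' coordinates: its voxel counts per axis, the (possibly anisotropic) voxel
#' sizes in millimetres, and the world position of the center of voxel
#' \code{(0,0,0)}.  The center of voxel \code{(i,j,k)} (0-based) is at
#' \code{origin + (i*d0, j*d1, k*d2)}.  The scanner axis is the third image
#' axis (z) in the canonical orientation.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (> 0).
#' @slot origin numeric(3), world mm of the center of voxel (0,0,0).
#' @export
setClass("ImageGrid",
  representation(shape = "integer", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be 3 positive integers")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive finite numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite numbers (mm)")
    TRUE
  })

#' Construct an ImageGrid
#'
#' @param shape integer(3) voxel counts.
#' @param voxelSize numeric(3) or scalar voxel size in mm.
#' @param origin numeric(3) world mm of the center of voxel (0,0,0); the
#'   default centers the grid on the world origin.
#' @return An \linkS4class{ImageGrid}.
#' @examples
#' g <- imageGrid(c(215L, 215L, 71L), 2.78)
#' voxelSize(g)
#' @export
imageGrid <- function(shape, voxelSize, origin = NULL) {
  shape <- as.integer(shape)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(origin)) origin <- -(shape - 1L) / 2 * voxelSize
  new("ImageGrid", shape = shape, voxelSize = voxelSize,
      origin = as.numeric(origin))
}

#' @rdname imageGrid
#' @param x an ImageGrid.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname imageGrid
#' @export
setMethod("gridShape", "ImageGrid", function(x) x@shape)

#' @rdname imageGrid
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname imageGrid
#' @export
setMethod("voxelSize", "ImageGrid", function(x) x@voxelSize)

#' @rdname imageGrid
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname imageGrid
#' @export
setMethod("gridOrigin", "ImageGrid", function(x) x@origin)

#' World coordinates of the voxel centers along one axis
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param axis axis index 1..3.
#' @return Numeric vector of world mm positions.
#' @export
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1L) * grid@voxelSize[axis]
}

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, %s mm, origin (%s) mm\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@voxelSize), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
})

# ---------------------------------------------------------------------------
# RaySet

#' A set of rays as paired world-coordinate endpoints
#'
#' The universal projector input: N rays given by start and end points in
#' world millimetres.  The low-level projectors are agnostic to any scanner
#' geometry; any ray set can be projected.
#'
#' @slot start N x 3 matrix of start points (mm).
#' @slot end N x 3 matrix of end points (mm).
#' @export
setClass("RaySet",
  representation(start = "matrix", end = "matrix"),
  validity = function(object) {
    if (ncol(object@start) != 3L || ncol(object@end) != 3L)
      return("start and end must have 3 columns")
    if (nrow(object@start) != nrow(object@end))
      return("start and end must have the same number of rows")
    if (any(!is.finite(object@start)) || any(!is.finite(object@end)))
      return("ray endpoints must be finite")
    len2 <- rowSums((object@end - object@start)^2)
    if (any(len2 <= 0))
      return("all rays must have positive length")
    TRUE
  })

#' Construct a RaySet
#'
#' @param start,end N x 3 matrices of world-mm endpoints.
#' @return A \linkS4class{RaySet}.
#' @export
raySet <- function(start, end) {
  start <- as.matrix(start)
  end <- as.matrix(end)
  storage.mode(start) <- "double"
  storage.mode(end) <- "double"
  dimnames(start) <- dimnames(end) <- NULL
  new("RaySet", start = start, end = end)
}

#' @rdname raySet
#' @param x a RaySet.
#' @export
setGeneric("rayStart", function(x) standardGeneric("rayStart"))
#' @rdname raySet
#' @export
setMethod("rayStart", "RaySet", function(x) x@start)
#' @rdname raySet
#' @export
setGeneric("rayEnd", function(x) standardGeneric("rayEnd"))
#' @rdname raySet
#' @export
setMethod("rayEnd", "RaySet", function(x) x@end)
#' @rdname raySet
#' @export
setGeneric("numRays", function(x) standardGeneric("numRays"))
#' @rdname raySet
#' @export
setMethod("numRays", "RaySet", function(x) nrow(x@start))

#' Reverse ray direction (swap start and end points)
#' @param x a RaySet.
#' @return A \linkS4class{RaySet} with start and end swapped.
#' @export
reverseRays <- function(x) raySet(x@end, x@start)

setMethod("show", "RaySet", function(object) {
  cat(sprintf("RaySet: %d rays (world mm)\n", nrow(object@start)))
})

# ---------------------------------------------------------------------------
# TOFSpec

#' Time-of-flight binning and kernel specification
#'
#' The TOF kernel is a Gaussian of standard deviation \code{sigmaMm}
#' (spatial, along the line of response) convolved with the rectangular TOF
#' bin of width \code{binWidthMm}, evaluated as a difference of error
#' functions and truncated to exactly zero beyond
#' \code{nSigmas * sigmaMm + binWidthMm / 2}.  Bin centers sit at offsets
#' \code{(b - (nBins-1)/2) * binWidthMm} from the LOR midpoint, positive
#' toward the ray end point.
#'
#' @slot nBins odd integer, number of TOF bins.
#' @slot binWidthMm bin width in mm.
#' @slot sigmaMm Gaussian kernel standard deviation in mm.
#' @slot nSigmas truncation radius in units of sigma (default 3).
#' @export
setClass("TOFSpec",
  representation(nBins = "integer", binWidthMm = "numeric",
                 sigmaMm = "numeric", nSigmas = "numeric"),
  validity = function(object) {
    if (length(object@nBins) != 1L || object@nBins < 1L ||
        object@nBins %% 2L == 0L)
      return("nBins must be a single odd positive integer")
    if (!(object@binWidthMm > 0)) return("binWidthMm must be > 0")
    if (!(object@sigmaMm > 0)) return("sigmaMm must be > 0")
    if (!(object@nSigmas > 0)) return("nSigmas must be > 0")
    TRUE
  })

#' Construct a TOFSpec
#'
#' @param nBins odd number of TOF bins.
#' @param binWidthMm TOF bin width in mm.
#' @param sigmaMm Gaussian kernel sigma in mm (see [sigmaFromFwhm()] and
#'   [fwhmPsToMm()] to derive it from a timing resolution).
#' @param nSigmas truncation radius in sigmas; default 3.
#' @return A \linkS4class{TOFSpec}.
#' @examples
#' tofSpec(29, fwhmPsToMm(169), sigmaFromFwhm(fwhmPsToMm(385)))
#' @export
tofSpec <- function(nBins, binWidthMm, sigmaMm, nSigmas = 3) {
  new("TOFSpec", nBins = as.integer(nBins), binWidthMm = as.numeric(binWidthMm),
      sigmaMm = as.numeric(sigmaMm), nSigmas = as.numeric(nSigmas))
}

#' @rdname tofSpec
#' @param x a TOFSpec.
#' @export
setGeneric("numBins", function(x) standardGeneric("numBins"))
#' @rdname tofSpec
#' @export
setMethod("numBins", "TOFSpec", function(x) x@nBins)

setMethod("show", "TOFSpec", function(object) {
  cat(sprintf("TOFSpec: %d bins x %.3g mm, sigma %.3g mm, truncated at %g sigma\n",
              object@nBins, object@binWidthMm, object@sigmaMm, object@nSigmas))
})

# ---------------------------------------------------------------------------
# ScannerModel

#' Cylindrical multi-ring PET scanner description
#'
#' Crystals are arranged on \code{nRings} rings of radius \code{ringRadiusMm}
#' around the z (scanner) axis.  Each ring holds
#' \code{modulesPerRing * crystalsPerModule} crystals; crystal 0 of every
#' ring sits at angle \code{angularOffset} from the positive x axis and
#' crystals are ordered counter-clockwise.  Ring z positions are centered on
#' \code{axialCenterOffsetMm}.  An optional per-module angular gap can be
#' modeled; it defaults to zero (equally spaced crystals).
#'
#' @slot nRings integer, number of detector rings.
#' @slot modulesPerRing integer.
#' @slot crystalsPerModule integer.
#' @slot ringRadiusMm numeric, ring radius in mm.
#' @slot axialPitchMm numeric, ring-to-ring spacing in mm.
#' @slot axialCenterOffsetMm numeric, world z of the scanner center.
#' @slot angularOffset numeric, angle of crystal 0 in radians.
#' @slot moduleGapRad numeric, angular gap between modules in radians.
#' @export
setClass("ScannerModel",
  representation(nRings = "integer", modulesPerRing = "integer",
                 crystalsPerModule = "integer", ringRadiusMm = "numeric",
                 axialPitchMm = "numeric", axialCenterOffsetMm = "numeric",
                 angularOffset = "numeric", moduleGapRad = "numeric"),
  validity = function(object) {
    if (object@nRings < 1L || object@modulesPerRing < 1L ||
        object@crystalsPerModule < 1L)
      return("ring, module and crystal counts must be >= 1")
    if (!(object@ringRadiusMm > 0)) return("ringRadiusMm must be > 0")
    if (!(object@axialPitchMm > 0)) return("axialPitchMm must be > 0")
    if (object@moduleGapRad < 0) return("moduleGapRad must be >= 0")
    if (object@modulesPerRing * object@moduleGapRad >= 2 * pi)
      return("module gaps exceed the full circle")
    TRUE
  })

#' Construct a ScannerModel
#'
#' @param nRings number of rings.
#' @param modulesPerRing modules per ring.
#' @param crystalsPerModule crystals per module.
#' @param ringRadiusMm ring radius in mm.
#' @param axialPitchMm axial crystal pitch (ring spacing) in mm.
#' @param axialCenterOffsetMm world z of the scanner center (default 0).
#' @param angularOffset angle of crystal 0 (radians, default 0).
#' @param moduleGapRad angular gap between modules (radians, default 0).
#' @return A \linkS4class{ScannerModel}.
#' @examples
#' sc <- scannerModel(36, 34, 16, 380, 5.56)
#' numCrystals(sc)
#' @export
scannerModel <- function(nRings, modulesPerRing, crystalsPerModule,
                         ringRadiusMm, axialPitchMm, axialCenterOffsetMm = 0,
                         angularOffset = 0, moduleGapRad = 0) {
  new("ScannerModel", nRings = as.integer(nRings),
      modulesPerRing = as.integer(modulesPerRing),
      crystalsPerModule = as.integer(crystalsPerModule),
      ringRadiusMm = as.numeric(ringRadiusMm),
      axialPitchMm = as.numeric(axialPitchMm),
      axialCenterOffsetMm = as.numeric(axialCenterOffsetMm),
      angularOffset = as.numeric(angularOffset),
      moduleGapRad = as.numeric(moduleGapRad))
}

#' @rdname scannerModel
#' @param x a ScannerModel.
#' @export
setGeneric("numCrystals", function(x) standardGeneric("numCrystals"))
#' @rdname scannerModel
#' @export
setMethod("numCrystals", "ScannerModel", function(x)
  x@nRings * x@modulesPerRing * x@crystalsPerModule)

#' @rdname scannerModel
#' @export
setGeneric("numTransaxial", function(x) standardGeneric("numTransaxial"))
#' @rdname scannerModel
#' @export
setMethod("numTransaxial", "ScannerModel", function(x)
  x@modulesPerRing * x@crystalsPerModule)

setMethod("show", "ScannerModel", function(object) {
  cat(sprintf(paste0(
    "ScannerModel: %d rings x %d modules x %d crystals = %d detectors,\n",
    "  radius %.1f mm, axial pitch %.3g mm\n"),
    object@nRings, object@modulesPerRing, object@crystalsPerModule,
    numCrystals(object), object@ringRadiusMm, object@axialPitchMm))
})

# ---------------------------------------------------------------------------
# SinogramSpec

#' Sinogram index space for a cylindrical scanner
#'
#' A span-1 sinogram indexed by (radial, view, plane [, TOF bin]).  Views and
#' signed radial offsets map to transaxial crystal pairs by the standard
#' interleaved convention; planes enumerate (ring_a, ring_b) combinations
#' with \code{|ring_a - ring_b| <= maxRingDiff}, ordered by ring difference
#' and then by axial position (see [planeRingTable()]).  The canonical
#' in-memory order is "PVR" (radial fastest); see [reorderSinogram()].
#'
#' @slot nRadial integer, radial elements.
#' @slot nViews integer, azimuthal views (= transaxial crystals / 2 for the
#'   standard interleaved sinogram).
#' @slot maxRingDiff integer, maximum |ring_a - ring_b|.
#' @slot axisOrder character, storage order permutation of "P","V","R"
#'   (slowest to fastest).
#' @slot tof a \linkS4class{TOFSpec} or NULL (list slot).
#' @export
setClass("SinogramSpec",
  representation(nRadial = "integer", nViews = "integer",
                 maxRingDiff = "integer", axisOrder = "character",
                 tof = "ANY"),
  validity = function(object) {
    if (object@nRadial < 1L || object@nViews < 1L)
      return("nRadial and nViews must be >= 1")
    if (object@maxRingDiff < 0L) return("maxRingDiff must be >= 0")
    if (!isValidAxisOrder(object@axisOrder))
      return("axisOrder must be a permutation of 'P','V','R'")
    if (!is.null(object@tof) && !is(object@tof, "TOFSpec"))
      return("tof must be NULL or a TOFSpec")
    TRUE
  })

isValidAxisOrder <- function(x) {
  length(x) == 1L && is.character(x) && nchar(x) == 3L &&
    setequal(strsplit(x, "")[[1]], c("P", "V", "R"))
}

#' Construct a SinogramSpec
#'
#' @param nRadial number of radial elements.
#' @param nViews number of views.
#' @param maxRingDiff maximum ring difference (default: nRings - 1 has to be
#'   set by the caller; use [nPlanes()] for the resulting plane count).
#' @param axisOrder storage order, default "PVR" (radial fastest).
#' @param tof optional \linkS4class{TOFSpec}.
#' @return A \linkS4class{SinogramSpec}.
#' @export
sinogramSpec <- function(nRadial, nViews, maxRingDiff, axisOrder = "PVR",
                         tof = NULL) {
  new("SinogramSpec", nRadial = as.integer(nRadial), nViews = as.integer(nViews),
      maxRingDiff = as.integer(maxRingDiff), axisOrder = as.character(axisOrder),
      tof = tof)
}

#' Number of sinogram planes for a scanner / spec combination
#'
#' Counts all (ring_a, ring_b) pairs with |difference| <= maxRingDiff:
#' \code{nRings + 2 * sum(nRings - d)} over d = 1..maxRingDiff.  For
#' maxRingDiff = nRings - 1 this equals nRings^2.
#'
#' @param spec a \linkS4class{SinogramSpec}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @return Integer plane count.
#' @export
nPlanes <- function(spec, scanner) {
  n <- scanner@nRings
  mrd <- min(spec@maxRingDiff, n - 1L)
  d <- seq_len(mrd)
  as.integer(n + if (mrd > 0L) 2L * sum(n - d) else 0L)
}

setMethod("show", "SinogramSpec", function(object) {
  cat(sprintf("SinogramSpec: %d radial x %d views, max ring diff %d, order %s%s\n",
              object@nRadial, object@nViews, object@maxRingDiff,
              object@axisOrder,
              if (is.null(object@tof)) "" else
                sprintf(", TOF (%d bins)", object@tof@nBins)))
})
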