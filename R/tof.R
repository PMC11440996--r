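# TOF kernel and the TOF extensions of the Joseph projector.

#' Convert a coincidence timing FWHM from picoseconds to millimetres
#'
#' A coincidence time difference t maps to a position offset c*t/2 along the
#' line of response (the factor 1/2 because both photons move).  Uses the
#' exact speed of light c = 299,792,458 m/s; e.g. 385 ps -> 57.71 mm.
#'
#' @param fwhmPs timing FWHM (or any time quantity) in picoseconds, > 0.
#' @return The corresponding spatial quantity in mm.
#' @examples
#' fwhmPsToMm(385)  # 57.71 mm
#' @export
fwhmPsToMm <- function(fwhmPs) {
  if (any(!is.finite(fwhmPs)) || any(fwhmPs <= 0))
    stop("time value must be positive and finite")
  fwhmPs * 1e-12 * 299792458 / 2 * 1e3
}

#' Gaussian FWHM to standard deviation
#'
#' @param fwhmMm FWHM in mm, > 0.
#' @return sigma = fwhm / (2 * sqrt(2 * log(2))) in mm.
#' @export
sigmaFromFwhm <- function(fwhmMm) {
  if (any(!is.finite(fwhmMm)) || any(fwhmMm <= 0))
    stop("FWHM must be positive and finite")
  fwhmMm / (2 * sqrt(2 * log(2)))
}

#' TOF bin weight: Gaussian kernel integrated over a rectangular bin
#'
#' The probability that an annihilation at signed distance \code{d} from a
#' TOF bin center is recorded in that bin, under a Gaussian timing kernel of
#' standard deviation \code{sigmaMm} convolved with the rectangular bin of
#' width \code{binWidthMm}:
#' \deqn{w(d) = \frac12\left[\mathrm{erf}\frac{d + w/2}{\sigma\sqrt2} -
#'   \mathrm{erf}\frac{d - w/2}{\sigma\sqrt2}\right]}
#' truncated to exactly 0 for \code{|d| > nSigmas*sigma + binWidth/2}.
#'
#' @param d signed distance(s) in mm from the bin center.
#' @param spec a \linkS4class{TOFSpec}.
#' @return Numeric vector of unitless weights in [0, 1].
#' @export
tofBinWeight <- function(d, spec) {
  stopifnot(is(spec, "TOFSpec"))
  cpp_tof_bin_weight(as.numeric(d), spec@binWidthMm, spec@sigmaMm, spec@nSigmas)
}

#' Signed center offsets of the TOF bins
#'
#' Bin b (0-based column index) has its center at
#' \code{(b - (nBins-1)/2) * binWidthMm} mm from the LOR midpoint, positive
#' toward the ray end point.
#'
#' @param spec a \linkS4class{TOFSpec}.
#' @return Numeric vector of length \code{nBins}.
#' @export
tofBinCenters <- function(spec) {
  (seq_len(spec@nBins) - 1 - (spec@nBins - 1) / 2) * spec@binWidthMm
}

#' TOF forward projection, sinogram mode (all bins per ray)
#'
#' Extends [forwardProject()] by weighting each plane's bilinear sample with
#' the TOF kernel evaluated at the signed distance between the plane
#' intersection point and each bin center (distances measured along the ray
#' from the LOR midpoint, positive toward the end point).  All bins are
#' filled while the volume is traversed once.
#'
#' @inheritParams forwardProject
#' @param spec a \linkS4class{TOFSpec}.
#' @return N x nBins matrix of TOF-weighted line integrals.
#' @export
forwardProjectTOF <- function(image, grid, rays, spec) {
  stopifnot(is(grid, "ImageGrid"), is(rays, "RaySet"), is(spec, "TOFSpec"))
  image <- checkImage(image, grid)
  cpp_joseph_fwd_tof_sino(as.vector(image), grid@shape, grid@voxelSize,
                          grid@origin, rays@start, rays@end, spec@nBins,
                          spec@binWidthMm, spec@sigmaMm, spec@nSigmas)
}

#' TOF back projection, sinogram mode (exact adjoint)
#'
#' @param values N x nBins matrix.
#' @inheritParams forwardProjectTOF
#' @return 3D array on \code{grid}.
#' @export
backProjectTOF <- function(values, rays, grid, spec) {
  stopifnot(is(grid, "ImageGrid"), is(rays, "RaySet"), is(spec, "TOFSpec"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  img <- cpp_joseph_back_tof_sino(values, grid@shape, grid@voxelSize,
                                  grid@origin, rays@start, rays@end,
                                  spec@nBins, spec@binWidthMm, spec@sigmaMm,
                                  spec@nSigmas)
  array(img, dim = grid@shape)
}

#' TOF forward projection, listmode mode (one bin per event)
#'
#' Evaluates, per event, only the contribution to that event's TOF bin:
#' identical arithmetic to the corresponding column of [forwardProjectTOF()],
#' so the two modes agree exactly.  TOF bins are signed: bin 0 is centered on
#' the LOR midpoint, positive bins lie toward the ray end point.
#'
#' @inheritParams forwardProjectTOF
#' @param tofBins integer vector of signed per-event TOF bins, within
#'   \code{[-(nBins-1)/2, (nBins-1)/2]}.
#' @return Numeric vector, one value per event.
#' @export
forwardProjectTOFLm <- function(image, grid, rays, tofBins, spec) {
  stopifnot(is(grid, "ImageGrid"), is(rays, "RaySet"), is(spec, "TOFSpec"))
  image <- checkImage(image, grid)
  cpp_joseph_fwd_tof_lm(as.vector(image), grid@shape, grid@voxelSize,
                        grid@origin, rays@start, rays@end,
                        as.integer(tofBins), spec@nBins, spec@binWidthMm,
                        spec@sigmaMm, spec@nSigmas)
}

#' TOF back projection, listmode mode (exact adjoint)
#'
#' @param values numeric vector, one value per event.
#' @inheritParams forwardProjectTOFLm
#' @return 3D array on \code{grid}.
#' @export
backProjectTOFLm <- function(values, rays, tofBins, grid, spec) {
  stopifnot(is(grid, "ImageGrid"), is(rays, "RaySet"), is(spec, "TOFSpec"))
  img <- cpp_joseph_back_tof_lm(as.numeric(values), grid@shape, grid@voxelSize,
                                grid@origin, rays@start, rays@end,
                                as.integer(tofBins), spec@nBins,
                                spec@binWidthMm, spec@sigmaMm, spec@nSigmas)
  array(img, dim = grid@shape)
}
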