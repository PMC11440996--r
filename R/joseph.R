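# Non-TOF Joseph projector pair (R wrappers over the compiled core).

checkImage <- function(image, grid) {
  if (is.null(dim(image))) dim(image) <- grid@shape
  if (!all(dim(image) == grid@shape))
    stop("image dimensions do not match the grid shape")
  storage.mode(image) <- "double"
  image
}

#' Joseph forward projection (non-TOF line integrals)
#'
#' For every ray the principal image axis (most parallel to the ray, ties
#' broken toward the lowest axis index) is traversed plane by plane; at each
#' plane crossing the image is bilinearly interpolated from the four nearest
#' voxels (zero outside the grid) and the sum is scaled by
#' \code{voxel/|u_p|}, the incidence-angle correction.  Plane crossings
#' beyond either ray endpoint are skipped.  Values are line integrals in
#' image-units times mm; rays missing the grid give 0.
#'
#' @param image 3D array matching \code{grid}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param rays a \linkS4class{RaySet}.
#' @return Numeric vector, one line integral per ray.
#' @seealso [backProject()] for the exactly matched adjoint.
#' @export
forwardProject <- function(image, grid, rays) {
  stopifnot(is(grid, "ImageGrid"), is(rays, "RaySet"))
  image <- checkImage(image, grid)
  cpp_joseph_fwd(as.vector(image), grid@shape, grid@voxelSize, grid@origin,
                 rays@start, rays@end)
}

#' Joseph back projection (exact adjoint of the forward projection)
#'
#' Computes \eqn{A^T y} where \eqn{A} is the exact linear map realized by
#' [forwardProject()]: every ray scatters its value into the image with the
#' same bilinear weights and step factor the forward projector uses, so the
#' inner-product identity \eqn{\langle Ax, y\rangle = \langle x, A^T
#' y\rangle} holds to double-precision rounding.
#'
#' @param values numeric vector, one value per ray.
#' @param rays a \linkS4class{RaySet}.
#' @param grid an \linkS4class{ImageGrid}.
#' @return 3D array on \code{grid}.
#' @export
backProject <- function(values, rays, grid) {
  stopifnot(is(grid, "ImageGrid"), is(rays, "RaySet"))
  if (length(values) != numRays(rays))
    stop("length of values must equal the number of rays")
  img <- cpp_joseph_back(as.numeric(values), grid@shape, grid@voxelSize,
                         grid@origin, rays@start, rays@end)
  array(img, dim = grid@shape)
}
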