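# Synthetic phantoms and the listmode event simulator.

#' NEMA-IQ-like digital phantom specification
#'
#' A background cylinder (axis = scanner z axis) plus a list of spheres
#' whose activity is a ratio of the background (0 = cold sphere).  Voxel
#' values are set by the innermost shape containing the voxel center.
#'
#' @slot bgRadiusMm background cylinder radius (mm).
#' @slot bgLengthMm background cylinder axial length (mm).
#' @slot bgActivity background activity (arbitrary units, >= 0).
#' @slot center numeric(3), world mm center of the cylinder.
#' @slot spheres data.frame with columns \code{x_mm}, \code{y_mm},
#'   \code{z_mm}, \code{diameter_mm}, \code{ratio}.
#' @export
setClass("PhantomSpec",
  representation(bgRadiusMm = "numeric", bgLengthMm = "numeric",
                 bgActivity = "numeric", center = "numeric",
                 spheres = "data.frame"),
  validity = function(object) {
    if (!(object@bgRadiusMm > 0) || !(object@bgLengthMm > 0))
      return("cylinder radius and length must be > 0")
    if (object@bgActivity < 0) return("activities must be >= 0")
    if (length(object@center) != 3L) return("center must have length 3")
    sp <- object@spheres
    need <- c("x_mm", "y_mm", "z_mm", "diameter_mm", "ratio")
    if (nrow(sp) > 0) {
      if (!all(need %in% names(sp)))
        return("spheres needs columns x_mm, y_mm, z_mm, diameter_mm, ratio")
      if (any(sp$ratio < 0) || any(sp$diameter_mm <= 0))
        return("sphere ratios must be >= 0 and diameters > 0")
      rad <- sqrt((sp$x_mm - object@center[1])^2 + (sp$y_mm - object@center[2])^2)
      if (any(rad + sp$diameter_mm / 2 > object@bgRadiusMm + 1e-9) ||
          any(abs(sp$z_mm - object@center[3]) + sp$diameter_mm / 2 >
              object@bgLengthMm / 2 + 1e-9))
        return("spheres must lie inside the background cylinder")
    }
    TRUE
  })

#' Construct a PhantomSpec
#'
#' @param bgRadiusMm,bgLengthMm,bgActivity background cylinder geometry and
#'   activity.
#' @param center world mm center of the cylinder (default origin).
#' @param spheres data.frame of spheres (see \linkS4class{PhantomSpec});
#'   empty by default.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(bgRadiusMm, bgLengthMm, bgActivity = 1,
                        center = c(0, 0, 0), spheres = NULL) {
  if (is.null(spheres))
    spheres <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                          z_mm = numeric(0), diameter_mm = numeric(0),
                          ratio = numeric(0))
  new("PhantomSpec", bgRadiusMm = as.numeric(bgRadiusMm),
      bgLengthMm = as.numeric(bgLengthMm), bgActivity = as.numeric(bgActivity),
      center = as.numeric(center), spheres = spheres)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: cylinder r=%.1f mm, L=%.1f mm, activity %.3g, %d sphere(s)\n",
              object@bgRadiusMm, object@bgLengthMm, object@bgActivity,
              nrow(object@spheres)))
})

#' Default NEMA-like image-quality phantom
#'
#' A 100 mm-radius, 180 mm-long background cylinder with six spheres of
#' 10, 13, 17, 22, 28 and 37 mm diameter on a 57.2 mm-radius hexagon in the
#' central plane, at 4:1 hot contrast.  These are this package's defaults
#' for a realistic NEMA-style event distribution; they are configurable and
#' not vendor values.
#'
#' @param hotRatio sphere-to-background activity ratio (default 4).
#' @param scale geometric scale factor applied to all lengths (use < 1 for
#'   desk-scale scanners).
#' @return A \linkS4class{PhantomSpec}.
#' @export
nemaPhantom <- function(hotRatio = 4, scale = 1) {
  d <- c(10, 13, 17, 22, 28, 37) * scale
  ang <- (0:5) * pi / 3
  r <- 57.2 * scale
  phantomSpec(
    bgRadiusMm = 100 * scale, bgLengthMm = 180 * scale, bgActivity = 1,
    spheres = data.frame(
      x_mm = r * cos(ang), y_mm = r * sin(ang), z_mm = 0,
      diameter_mm = d, ratio = hotRatio
    )
  )
}

#' Rasterize a phantom onto an image grid
#'
#' Voxel value = activity of the innermost shape containing the voxel
#' center: spheres (in table order, later rows override) over the
#' background cylinder over zero.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param grid an \linkS4class{ImageGrid}.
#' @return 3D activity image.
#' @export
rasterizePhantom <- function(spec, grid) {
  stopifnot(is(spec, "PhantomSpec"), is(grid, "ImageGrid"))
  x <- axisCoords(grid, 1) - spec@center[1]
  y <- axisCoords(grid, 2) - spec@center[2]
  z <- axisCoords(grid, 3) - spec@center[3]
  img <- array(0, grid@shape)
  inCyl <- outer(x^2, y^2, "+") <= spec@bgRadiusMm^2
  inZ <- abs(z) <= spec@bgLengthMm / 2
  for (k in which(inZ)) img[, , k][inCyl] <- spec@bgActivity
  sp <- spec@spheres
  for (i in seq_len(nrow(sp))) {
    d2 <- outer(outer((x + spec@center[1] - sp$x_mm[i])^2,
                      (y + spec@center[2] - sp$y_mm[i])^2, "+"),
                (z + spec@center[3] - sp$z_mm[i])^2, "+")
    img[d2 <= (sp$diameter_mm[i] / 2)^2] <- sp$ratio[i] * spec@bgActivity
  }
  img
}

#' Simulate listmode events from an activity image
#'
#' Computes the expectation sinogram \eqn{\lambda} (TOF forward projection
#' over the full sinogram of the configured scanner, optionally smoothed by
#' a resolution model), then draws events from it: multinomially with a
#' fixed total \code{nEvents} (the default, matching a prompt-count-matched
#' acquisition), or per-bin Poisson with the same expected total.  Sampled
#' bins are expanded to per-event crystal pairs and signed TOF bins and
#' optionally shuffled.  Fully deterministic for a fixed seed.
#'
#' @param image 3D activity image (>= 0, positive total forward mass).
#' @param grid an \linkS4class{ImageGrid}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @param spec a \linkS4class{SinogramSpec}; its \code{tof} slot (if any)
#'   sets the TOF binning.
#' @param nEvents number of events (exact in multinomial mode, expected in
#'   Poisson mode).
#' @param seed optional integer RNG seed.
#' @param shuffle randomly permute the event order (default TRUE).
#' @param mode "multinomial" (default) or "poisson".
#' @param resFwhmMm resolution-model FWHM applied to the image before
#'   projection (default 0).
#' @return list with \code{events} (data.frame det_a, det_b, tof_bin) and
#'   \code{lambda} (expectation sinogram, canonical order, scaled to sum to
#'   \code{nEvents}).
#' @export
simulateListmode <- function(image, grid, scanner, spec, nEvents, seed = NULL,
                             shuffle = TRUE, mode = c("multinomial", "poisson"),
                             resFwhmMm = 0) {
  mode <- match.arg(mode)
  stopifnot(nEvents >= 0, all(image >= 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- fullSinogramIndices(spec, scanner)
  rays <- sinoIndexToRay(spec, scanner, idx)
  xs <- gaussianSmooth(checkImage(image, grid), grid, resFwhmMm)
  tof <- spec@tof
  np <- nPlanes(spec, scanner)
  lam <- if (is.null(tof)) {
    array(forwardProject(xs, grid, rays),
          dim = c(spec@nRadial, spec@nViews, np))
  } else {
    array(forwardProjectTOF(xs, grid, rays, tof),
          dim = c(spec@nRadial, spec@nViews, np, tof@nBins))
  }
  tot <- sum(lam)
  if (!(tot > 0)) stop("all-zero expectation sinogram")
  p <- as.vector(lam) / tot
  counts <- if (mode == "multinomial") {
    if (nEvents > 0) as.vector(stats::rmultinom(1, nEvents, p))
    else numeric(length(p))
  } else {
    stats::rpois(length(p), nEvents * p)
  }
  dim(counts) <- dim(lam)
  events <- sinogramToEvents(counts, spec, scanner)
  if (shuffle && nrow(events) > 1L)
    events <- events[sample.int(nrow(events)), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, lambda = lam / tot * nEvents)
}
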