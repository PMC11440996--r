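# File formats, configuration presets, sinogram memory layouts, benchmark.

#' Reorder a sinogram between storage layouts
#'
#' Layout names list the axes from slowest to fastest in memory ("PVR":
#' plane slowest, radial fastest).  R arrays are column-major (first index
#' fastest), so a "PVR" array has dim (nRadial, nViews, nPlanes) -- the
#' package's canonical order.  A trailing TOF-bin axis, if present, is left
#' in place.  The operation is a pure axis permutation: values are
#' unchanged and any round trip is lossless.
#'
#' @param sino 3D (or 4D, with trailing TOF axis) sinogram array.
#' @param from,to layout strings, permutations of "P", "V", "R".
#' @return The reordered array.
#' @examples
#' s <- array(1:24, c(2, 3, 4))              # PVR: 2 radial, 3 views, 4 planes
#' identical(reorderSinogram(reorderSinogram(s, "PVR", "VRP"), "VRP", "PVR"), s)
#' @export
reorderSinogram <- function(sino, from, to) {
  if (!isValidAxisOrder(from) || !isValidAxisOrder(to))
    stop("layouts must be permutations of 'P', 'V', 'R'")
  d <- dim(sino)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("sinogram must be a 3D or 4D array")
  if (from == to) return(sino)
  # axis meaning of array dim i is the (4-i)-th letter of the layout string
  fromAx <- rev(strsplit(from, "")[[1]])
  toAx <- rev(strsplit(to, "")[[1]])
  perm <- match(toAx, fromAx)
  aperm(sino, c(perm, if (length(d) == 4L) 4L))
}

# ---------------------------------------------------------------------------
# Images

#' Write / read an image as NIfTI
#'
#' The voxel size and origin are stored in (and recovered from) the NIfTI
#' affine; the canonical axis orientation (scanner axis = third image axis)
#' is kept as-is, no axis flips are applied.
#'
#' @param image 3D array.
#' @param grid an \linkS4class{ImageGrid}.
#' @param path file path (.nii or .nii.gz).
#' @return \code{readImageNifti} returns a list with \code{image} and
#'   \code{grid}.
#' @export
writeImageNifti <- function(image, grid, path) {
  image <- checkImage(image, grid)
  aff <- diag(c(grid@voxelSize, 1))
  aff[1:3, 4] <- grid@origin
  nii <- RNifti::asNifti(image)
  nii <- RNifti::`pixdim<-`(nii, grid@voxelSize)
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(aff, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname writeImageNifti
#' @export
readImageNifti <- function(path) {
  nii <- RNifti::readNifti(path)
  aff <- RNifti::xform(nii)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- imageGrid(dim(nii)[1:3], vox, aff[1:3, 4])
  list(image = array(as.vector(nii), dim(nii)[1:3]), grid = grid)
}

#' Write / read an image as raw doubles plus a JSON sidecar
#'
#' The sidecar (\code{<path>.json}) records \code{shape},
#' \code{voxel_size_mm} and \code{origin_mm}; the data file holds the array
#' in column-major float64.
#'
#' @inheritParams writeImageNifti
#' @return \code{readImageRaw} returns a list with \code{image} and
#'   \code{grid}.
#' @export
writeImageRaw <- function(image, grid, path) {
  image <- checkImage(image, grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(image), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(shape = grid@shape, voxel_size_mm = grid@voxelSize,
         origin_mm = grid@origin),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeImageRaw
#' @export
readImageRaw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  grid <- imageGrid(meta$shape, meta$voxel_size_mm, meta$origin_mm)
  list(image = array(v, meta$shape), grid = grid)
}

# ---------------------------------------------------------------------------
# Rays and events (CSV)

#' Write / read a RaySet as CSV (columns xs, ys, zs, xe, ye, ze in mm)
#' @param rays a \linkS4class{RaySet}.
#' @param path file path.
#' @export
writeRaysCsv <- function(rays, path) {
  df <- data.frame(xs = rays@start[, 1], ys = rays@start[, 2],
                   zs = rays@start[, 3], xe = rays@end[, 1],
                   ye = rays@end[, 2], ze = rays@end[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRaysCsv
#' @export
readRaysCsv <- function(path) {
  df <- utils::read.csv(path)
  raySet(as.matrix(df[, c("xs", "ys", "zs")]),
         as.matrix(df[, c("xe", "ye", "ze")]))
}

#' Write / read listmode events as CSV (columns det_a, det_b, tof_bin)
#' @param events events data.frame.
#' @param path file path.
#' @export
writeEventsCsv <- function(events, path) {
  utils::write.csv(events[, c("det_a", "det_b", "tof_bin")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCsv
#' @export
readEventsCsv <- function(path) {
  utils::read.csv(path, colClasses = "integer")
}

# ---------------------------------------------------------------------------
# Configuration

#' Read a scanner / sinogram / TOF / image configuration
#'
#' YAML with sections \code{scanner} (n_rings, modules_per_ring,
#' crystals_per_module, ring_radius_mm, axial_pitch_mm and optional
#' axial_center_offset_mm, angular_offset_rad, module_gap_rad),
#' \code{sinogram} (n_radial, n_views, max_ring_difference, axis_order),
#' optional \code{tof} (num_tofbins, tofbin_width_mm or tofbin_width_ps,
#' sigma_mm or fwhm_ps, num_sigmas) and optional \code{image} (shape,
#' voxel_size_mm, origin_mm).
#'
#' @param path YAML file path.
#' @return list with elements \code{scanner}, \code{sinogram} (its
#'   \code{tof} slot populated when a tof section exists), \code{tof},
#'   \code{grid} (NULL when absent) and \code{name}.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  s <- cfg$scanner
  scanner <- scannerModel(
    nRings = s$n_rings, modulesPerRing = s$modules_per_ring,
    crystalsPerModule = s$crystals_per_module,
    ringRadiusMm = s$ring_radius_mm, axialPitchMm = s$axial_pitch_mm,
    axialCenterOffsetMm = s$axial_center_offset_mm %||% 0,
    angularOffset = s$angular_offset_rad %||% 0,
    moduleGapRad = s$module_gap_rad %||% 0)
  tof <- NULL
  if (!is.null(cfg$tof)) {
    t <- cfg$tof
    w <- t$tofbin_width_mm %||% fwhmPsToMm(t$tofbin_width_ps)
    sg <- t$sigma_mm %||% sigmaFromFwhm(fwhmPsToMm(t$fwhm_ps))
    tof <- tofSpec(t$num_tofbins, w, sg, t$num_sigmas %||% 3)
  }
  g <- cfg$sinogram
  spec <- sinogramSpec(g$n_radial, g$n_views,
                       g$max_ring_difference %||% (s$n_rings - 1L),
                       g$axis_order %||% "PVR", tof = tof)
  grid <- NULL
  if (!is.null(cfg$image))
    grid <- imageGrid(cfg$image$shape, cfg$image$voxel_size_mm,
                      cfg$image$origin_mm)
  list(scanner = scanner, sinogram = spec, tof = tof, grid = grid,
       name = cfg$name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a shipped configuration preset
#'
#' Available presets: \code{"discovery-mi-like"} (36 rings of 34 x 16
#' crystals, 380 mm radius, 415 x 272 sinogram, 29 TOF bins of 169 ps at
#' 385 ps FWHM -- the crystal pitches are approximate, chosen for a 20 cm
#' axial FOV) and \code{"toy-32crystal"} (a desk-scale 4-ring scanner for
#' tests and examples).
#'
#' @param name preset name.
#' @return As [readConfig()].
#' @export
presetConfig <- function(name = c("discovery-mi-like", "toy-32crystal")) {
  name <- match.arg(name)
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "petray", mustWork = TRUE)
  readConfig(path)
}

# ---------------------------------------------------------------------------
# Benchmark harness

# Permute an image + grid + ray coordinates so that the scanner axis lies on
# image array axis (symMode + 1); axis 0 is the memory-fastest axis in R.
axisPermForSymMode <- function(symMode) {
  switch(as.character(symMode),
         "0" = c(3L, 2L, 1L),
         "1" = c(1L, 3L, 2L),
         "2" = c(1L, 2L, 3L),
         stop("symmetry axis mode must be 0, 1 or 2"))
}

#' Benchmark projector timings across memory layouts
#'
#' Times forward and back projections of a (subset) sinogram for every
#' combination of sinogram storage order and image symmetry-axis mode
#' (which image array axis carries the scanner axial direction).  All
#' layout cells compute the same numbers -- only timings may differ; the
#' function checks each cell's values against the canonical layout and
#' errors if they disagree.  Rays whose direction ties two principal axes
#' exactly (e.g. perfect 45 degree LORs) are excluded from the equality
#' check: the tie-break is by axis index, so their discretization
#' legitimately follows the axis relabeling.  Timings are reported, never
#' asserted.
#'
#' @param image 3D activity image on \code{grid} (canonical orientation).
#' @param grid an \linkS4class{ImageGrid}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @param spec a \linkS4class{SinogramSpec} (TOF used when present).
#' @param views 0-based view indices to project (default: all views).
#' @param orders sinogram layout strings to sweep.
#' @param symModes symmetry-axis modes to sweep (subset of 0:2).
#' @param repeats repetitions per cell; mean and sd are reported.
#' @return data.frame with one row per (order, symmetry mode): mean and sd
#'   of forward, back and combined wall times in seconds.
#' @export
benchmarkProjectors <- function(image, grid, scanner, spec, views = NULL,
                                orders = c("PVR", "VRP", "RVP"),
                                symModes = 0:2, repeats = 3) {
  idx <- fullSinogramIndices(spec, scanner, views)
  rays0 <- sinoIndexToRay(spec, scanner, idx)
  tof <- spec@tof
  fwd0 <- if (is.null(tof)) forwardProject(image, grid, rays0)
          else forwardProjectTOF(image, grid, rays0, tof)
  # rays with an unambiguous principal axis (no exact |u| tie)
  u <- abs(rays0@end - rays0@start)
  u <- u / sqrt(rowSums(u^2))
  us <- t(apply(u, 1, sort, decreasing = TRUE))
  untied <- us[, 1] - us[, 2] > 1e-9
  if (is.null(views)) views <- 0:(spec@nViews - 1L)
  np <- nPlanes(spec, scanner)
  sinoDim <- c(spec@nRadial, length(views), np)
  rows <- list()
  for (ord in orders) for (sm in symModes) {
    perm <- axisPermForSymMode(sm)
    g <- imageGrid(grid@shape[perm], grid@voxelSize[perm], grid@origin[perm])
    img <- aperm(checkImage(image, grid), perm)
    # traverse the rays in the storage order of the requested layout
    pos <- array(seq_len(prod(sinoDim)), sinoDim)
    rord <- as.vector(reorderSinogram(pos, "PVR", ord))
    rays <- raySet(rays0@start[rord, perm, drop = FALSE],
                   rays0@end[rord, perm, drop = FALSE])
    tf <- tb <- numeric(repeats)
    for (r in seq_len(repeats)) {
      t0 <- proc.time()[["elapsed"]]
      fwd <- if (is.null(tof)) forwardProject(img, g, rays)
             else forwardProjectTOF(img, g, rays, tof)
      t1 <- proc.time()[["elapsed"]]
      bp <- if (is.null(tof)) backProject(fwd, rays, g)
            else backProjectTOF(fwd, rays, g, tof)
      t2 <- proc.time()[["elapsed"]]
      tf[r] <- t1 - t0
      tb[r] <- t2 - t1
    }
    if (!is.null(dim(fwd))) {
      fwd[rord, ] <- fwd
      mism <- max(abs(fwd[untied, ] - fwd0[untied, ]))
    } else {
      fwd[rord] <- fwd
      mism <- max(abs(fwd[untied] - fwd0[untied]))
    }
    if (mism > 1e-10 * max(abs(fwd0)))
      stop("layout sweep produced values differing from the canonical layout")
    sdv <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      order = ord, sym_mode = sm,
      forward_mean_s = mean(tf), forward_sd_s = sdv(tf),
      back_mean_s = mean(tb), back_sd_s = sdv(tb),
      combined_mean_s = mean(tf + tb), combined_sd_s = sdv(tf + tb))
  }
  do.call(rbind, rows)
}

#' Bar chart of benchmark timings
#'
#' @param bench output of [benchmarkProjectors()].
#' @param what which timing column group to plot.
#' @export
plotBenchmark <- function(bench, what = c("combined", "forward", "back")) {
  what <- match.arg(what)
  m <- bench[[paste0(what, "_mean_s")]]
  s <- bench[[paste0(what, "_sd_s")]]
  lab <- paste(bench$order, bench$sym_mode, sep = "/")
  bp <- graphics::barplot(m, names.arg = lab, las = 2,
                          ylab = sprintf("%s time (s)", what),
                          ylim = c(0, max(m + s) * 1.1))
  graphics::arrows(bp, m - s, bp, m + s, angle = 90, code = 3, length = 0.03)
  invisible(bp)
}
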