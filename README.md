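# petray

Joseph ray-driven projectors for 3D PET — non-TOF and time-of-flight (TOF),
sinogram and listmode — with back projectors that are the **exact adjoints**
of the forward projectors, plus the surrounding machinery needed to use and
validate them end to end: a cylindrical multi-ring scanner geometry model
with interleaved sinogram indexing, MLEM/OSEM reconstruction with an
image-based Gaussian resolution model, a synthetic NEMA-like phantom and
seeded listmode event simulator, sinogram memory-layout utilities and a
projector benchmark harness.

It is aimed at researchers in emission-tomography image reconstruction who
need a transparent, fully testable reference implementation of the
projection operators that sit at the core of iterative PET reconstruction.

## The method

For a ray with unit direction *u*, Joseph's method picks the image axis *p*
most parallel to the ray and steps through the volume plane by plane along
it. At each plane the intersection point is bilinearly interpolated from
its four nearest voxels (zero outside the grid), and the sum is scaled by
Δp/|u_p|, the incidence-angle correction. The TOF extension weights each
plane's contribution per TOF bin with a Gaussian-convolved-with-rect
kernel,

w(d) = ½[erf((d + w/2)/(σ√2)) − erf((d − w/2)/(σ√2))],

truncated beyond ±3σ, where *d* is the signed distance from the
intersection point to the bin center (measured from the LOR midpoint). In
sinogram mode all bins of a ray are filled in one traversal; in listmode
mode only the event's own bin is evaluated. Back projections scatter with
identical weights, so ⟨Ax, y⟩ = ⟨x, Aᵀy⟩ holds to ~10⁻¹⁶ relative —
matched pairs are required for convergent statistical reconstruction.
Reconstruction uses the standard OSEM update
x′ = x/S_k · GᵀPᵀMᵀ( y_k / (M P G x + s_k) ) with equally spaced view
subsets (sinogram) or event strides (listmode).

## Worked example

```r
library(petray)

## clinical-scale geometry preset
cfg <- presetConfig("discovery-mi-like")
cfg$scanner
#> ScannerModel: 36 rings x 34 modules x 16 crystals = 19584 detectors,
#>   radius 380.0 mm, axial pitch 5.56 mm
nPlanes(cfg$sinogram, cfg$scanner)   # span-1 planes (all ring pairs)
#> [1] 1296
round(fwhmPsToMm(385), 2)            # 385 ps timing FWHM along the LOR, mm
#> [1] 57.71
subsetViews(272, 34, 0)              # one OSEM subset: 8 equally spaced views
#> [1]   0  34  68 102 136 170 204 238

## simulate and reconstruct a desk-scale phantom
toy <- presetConfig("toy-32crystal")
ph  <- phantomSpec(30, 36, 1, spheres = data.frame(
  x_mm = 12, y_mm = 0, z_mm = 0, diameter_mm = 16, ratio = 4))
img <- rasterizePhantom(ph, toy$grid)
sim <- simulateListmode(img, toy$grid, toy$scanner, toy$sinogram,
                        2e5, seed = 1)
head(sim$events, 3)
#>   det_a det_b tof_bin
#> 1    78    31       0
#> 2    70    88      -1
#> 3    68   117      -2
rec  <- osemLm(sim$events, toy$scanner, toy$sinogram, toy$grid,
               nIterations = 4, nSubsets = 8)
post <- gaussianSmooth(rec$image, toy$grid, 8)   # post-filter
round(mean(post[img == 4]), 2)  # mean in the 4:1 hot sphere
#> [1] 3.59
round(mean(post[img == 1]), 2)  # mean in the background cylinder
#> [1] 1.27
```

The reconstructed hot sphere reads 3.59 against a background of 1.27 — an
apparent contrast of 2.8:1 rather than the true 4:1, the expected effect of
partial volume (a 16 mm sphere on 4 mm voxels) and the 8 mm post-filter on
noisy 2×10⁵-event data.

A command-line interface over the same functions ships with the package
(`system.file("scripts", "petray-cli.R", package = "petray")`) with
subcommands `make-phantom`, `simulate`, `fwd`, `back`, `fwd-tof`,
`back-tof`, `osem-sino`, `osem-lm` and `benchmark`; every invocation
appends a JSON run record (command, config hash, seed, wall time).

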