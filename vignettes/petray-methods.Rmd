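---
title: "Ray-driven TOF PET projection and reconstruction with petray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-driven TOF PET projection and reconstruction with petray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petray)
```

## The projection model

Iterative PET reconstruction spends nearly all of its time evaluating a
linear forward model: line integrals of an activity image along the lines of
response (LORs) joining detector pairs.  petray implements Joseph's
ray-driven method for these integrals.  For each ray the image axis most
parallel to the ray direction $u$ is chosen as the *principal axis* $p$ (at
an exact tie the lowest axis index wins, a determinism choice), and the
volume is traversed plane by plane along that axis.  At every plane crossing
the in-plane intersection point is interpolated bilinearly from its four
nearest voxels — weights that fall outside the grid contribute zero, so
partial intersections taper smoothly instead of jumping at the image edge —
and the accumulated sum is scaled by $\Delta_p / |u_p|$, the 3D
generalization of the incidence-angle correction ($\Delta_p$ is the voxel
size along $p$; $\Delta_p/|u_p|$ is exactly the distance between consecutive
plane crossings along the ray).  Voxel sizes may be anisotropic.

The projectors take nothing but a list of start/end world coordinates
(`RaySet`), so any scanner geometry can be modeled; the `ScannerModel` /
`SinogramSpec` layer is one producer of such ray sets, not a requirement.

Two boundary details are deliberate:

* Plane crossings outside the segment between the ray endpoints are
  skipped.  Endpoints are detector surfaces, normally outside the field of
  view, so this only matters for rays that start or end inside the volume;
  there the integral carries an $O(\Delta)$ discretization error because no
  fractional first/last plane step is taken.
* The back projector scatters with *identical* weights and scaling, making
  it the exact transpose of the forward map.  The inner-product identity
  $\langle Ax, y\rangle = \langle x, A^T y\rangle$ holds to double-precision
  rounding ($<10^{-12}$ relative, measured $\sim 10^{-16}$), for every grid,
  voxel anisotropy and principal axis.  All accumulation is in double
  precision.  Matched pairs are what make the MLEM/OSEM convergence theory
  applicable.

A known worst case: a ray lying exactly on a 45° cell diagonal, sampled
exactly at cell corners, places every interpolation point on a kink of the
bilinear interpolant; agreement with a fine-step line-integral quadrature
degrades from $\lesssim 0.5\%$ (generic oblique rays) to a few percent
there.  This is intrinsic to Joseph's method, not an implementation
artifact.

## Time-of-flight weighting

TOF detection localizes the annihilation along the LOR.  The kernel is a
Gaussian (detector timing uncertainty, standard deviation `sigmaMm` in mm
along the LOR) convolved with the rectangular TOF bin of width
`binWidthMm`, i.e. a difference of error functions:

$$ w(d) = \tfrac12\!\left[\operatorname{erf}\!\frac{d + w/2}{\sigma\sqrt2}
   - \operatorname{erf}\!\frac{d - w/2}{\sigma\sqrt2}\right] $$

with $d$ the signed distance from a voxel (plane intersection point) to the
bin center.  Conversions: a coincidence timing FWHM in ps maps to mm via
$c\,t/2$ with the exact speed of light (`fwhmPsToMm()`; 385 ps → 57.71 mm —
note that with the rounded $c \approx 3\times10^8$ m/s, 169 ps gives
25.4 mm rather than our 25.33 mm), and $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln
2})$ (`sigmaFromFwhm()`).

Choices that matter:

* **Distance origin.** TOF distances are measured from the midpoint of the
  start→end segment, positive toward the end point; bin $b$ (signed) is
  centered at $b \cdot w$.  The midpoint is the symmetric choice for an odd
  bin count.
* **Truncation.** The kernel is set to exactly zero beyond
  `nSigmas * sigma + binWidth/2` (default 3σ), applied per voxel–bin pair.
  Truncating the weight rather than clipping the plane loop keeps forward
  and adjoint exactly matched.  The price is a deficit of up to the kernel
  mass beyond 3σ (≈0.27% of a ray's total) in the sum over bins; widening
  to 6σ recovers it, and values are non-decreasing in `nSigmas`.
* **One kernel evaluation per plane.** The TOF weight is evaluated at the
  plane intersection point and shared by the four bilinear neighbours,
  matching the plane-stepping structure.
* **Sinogram vs listmode.** Sinogram mode fills all bins of a ray in one
  traversal; listmode mode evaluates only the event's bin.  Both share the
  same kernel arithmetic, so a listmode value equals the corresponding
  sinogram column bit-for-bit up to summation order ($<10^{-12}$ relative,
  measured $\sim10^{-16}$).

## Scanner geometry and sinogram indexing

`ScannerModel` describes a cylindrical multi-ring scanner: crystal $t$ of
every ring at angle $2\pi t/N$ (plus a configurable offset, optional
per-module angular gaps, default none), rings spaced by the axial pitch and
centered on a configurable world $z$.  The shipped `discovery-mi-like`
preset reproduces a 36-ring, 34×16-crystal, 380 mm-radius system with a
415×272 span-1 sinogram, 29 TOF bins of 169 ps and a 385 ps FWHM kernel.
The crystal pitches are approximate (chosen to give a 20 cm axial FOV over
36 rings, axial pitch ≈ 5.56 mm); no public pitch value was available to
us.  One published figure modeled the TOF resolution as 375 ps in a caption
while the system description says 385 ps; the preset uses 385 ps.

Transaxial indexing follows the standard interleaved convention: for $N$
transaxial crystals, view $v \in [0, N/2)$ and signed radial offset
$s = \text{radial} - (n_R-1)/2$,

$$ c_a = \left(v + \lfloor (s+1)/2 \rfloor\right) \bmod N, \qquad
   c_b = \left(v - \lfloor s/2 \rfloor + N/2\right) \bmod N . $$

This reproduces 272 views from 544 crystals and is invertible on its image
(`crystalPairToSino()`), verified by exhaustive enumeration on a toy ring.
Axially, span-1 planes enumerate all ring pairs with
$|r_a - r_b| \le$ `maxRingDiff`, ordered by ring difference and then axial
position.  For 36 rings this gives $36^2 = 1296$ planes; the vendor
convention that prints 1,292 planes for the same scanner is not public, so
the plane count is derived from `maxRingDiff` and 1,292 is never asserted.
The resulting full-sinogram LOR count (146.3 million) is within 0.3% of the
commonly quoted 146 million.

OSEM view subsets are equally spaced (`subsetViews()`): subset $k$ of $n$
holds views $k, k+n, k+2n, \dots$ — 8 views per subset for 272 views and 34
subsets.  If $n$ does not divide the view count, subset sizes differ by at
most one.

## MLEM / OSEM reconstruction

The forward model is $\bar y = M P G x + s$: $G$ a shift-invariant
image-based Gaussian resolution model (separable convolution, truncated at
4σ, unit-sum kernel, zero-padded — hence exactly self-adjoint and
mass-conserving away from the image border), $P$ the Joseph projector
(non-TOF or TOF, sinogram or listmode), $M$ diagonal multiplicative factors
(the only entry point for attenuation/normalization; no physics is
modeled), and $s \ge 0$ an additive contamination term.  The update is the
standard multiplicative EM step

$$ x' = \frac{x}{S_k}\, G^T P^T M^T \frac{y_k}{M P G x + s_k},
   \qquad S_k = G^T P^T M^T \mathbf 1 , $$

with subsets over views (sinogram) or event-index strides (listmode; event
$i$ → subset $i \bmod n$, which matches the equally-spaced spirit of view
subsets and is robust to shuffled files).  The listmode sensitivity uses
the full non-TOF LOR set divided by the subset count — the standard
listmode-OSEM choice, exact up to the TOF truncation deficit above — and
can be coarsened with a view stride, flagged as an approximation.
Numerical guards: denominators are clamped at $10^{-10}\,\mathrm{median}
(\bar y)$, bins with $y = 0$ contribute the $0/0$ limit 0, and voxels with
non-positive sensitivity are left unchanged.  Updates preserve
non-negativity; with one subset the Poisson log-likelihood is monotone
(verified numerically over 20 iterations on seeded noisy data).

## Synthetic data

`nemaPhantom()` builds a NEMA-IQ-like digital phantom: a 100 mm-radius,
180 mm-long background cylinder with six spheres (10–37 mm diameter) at 4:1
hot contrast on a 57.2 mm hexagon.  These defaults are this package's
choices for a realistic event distribution, not vendor values.
`simulateListmode()` computes the expectation sinogram λ with the TOF
forward projector over the full sinogram of the configured scanner and
draws events multinomially with probabilities λ/Σλ, so the prompt count is
exact, as in a count-matched benchmark; a per-bin Poisson mode exists
behind a flag.  Sampling is seeded and bit-reproducible.  Attenuation,
scatter, randoms, positron range and detector blurring are *not* simulated
— the phantom exercises the statistical structure the reconstruction
assumes (independent counts with a known linear expectation), so passing
tests demonstrate internal consistency of projectors, sampler and
reconstruction, not robustness to real-data physics.

## Problem sizes used in validation

The validation suite runs on a desk-scale toy scanner (preset
`toy-32crystal`: 4 rings × 32 transaxial crystals, 60 mm radius, 15×16×16
sinogram, 11 TOF bins of 20 mm, σ = 12 mm) with a 25×25×7 image at
(4, 4, 6) mm voxels — sizes chosen so every end-to-end check (including a
million-event simulation and full OSEM runs) completes in seconds while
leaving every code path identical to the clinical-scale configuration.
The toy TOF bin grid spans the in-FOV ray segments plus the 3σ kernel
margin, mirroring clinical systems, so TOF bin sums reproduce non-TOF
values to the truncation deficit.

Two validation choices deserve a note:

* The listmode-vs-sinogram OSEM comparison uses a 13×13×5 image so the
  system (3,840 LORs vs 845 voxels) is overdetermined.  On an
  underdetermined grid both modes converge to *data-consistent* solutions
  that differ inside the null space of the system matrix, and no agreement
  bound holds; this is a property of EM on underdetermined systems, not of
  the projectors.  A finite event list can only represent noiseless data
  as integer counts, so the comparison scales the noiseless sinogram to
  10⁶ events and rounds; at ~350 counts per nonzero bin the rounding
  inconsistency is negligible against the <1% agreement criterion.
* Sphere-contrast recovery is assessed on sphere-core and eroded
  background masks to avoid partial-volume voxels at 4 mm resolution.

## Limitations

* Only Joseph's method is implemented (no Siddon, distance-driven or
  tube-of-response projectors) and only Gaussian TOF kernels.
* Single-host, single-threaded execution; results are independent of ray
  ordering and chunking by construction, which substitutes for the
  concurrency contracts of parallel implementations.
* Listmode event tables and ray sets are read/written as CSV, images as
  NIfTI or raw float64 + JSON sidecar.
* The $O(\Delta)$ endpoint effect for rays terminating inside the volume,
  and the 45° corner-diagonal worst case, as described above.
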