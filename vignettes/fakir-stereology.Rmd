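---
title: "Fakir line-probe stereology and watershed morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fakir line-probe stereology and watershed morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fakir3d)
```

## The estimation problem

Comparative neuroanatomy needs volumes and surface areas of the brain, its
major compartments (prosencephalon, mesencephalon, rhombencephalon) and the
endoneurocranial space, measured from tomographic data (MR for soft tissue,
micro-CT for bone). Manual delineation is laborious and operator dependent;
`fakir3d` implements the two quantitative stages that replace it:

1. **Fakir line-probe stereology** — unbiased volume and surface estimation
   of a segmented 3D binary mask from its intersections with lattices of
   parallel line probes ("fakir bed of nails"), and
2. **marker-controlled watershed segmentation** — automated extraction of
   the endocranial cavity from a CT-like volume, whose cavity mask is then
   measured with the same stereological machinery or by voxel counting.

A third module computes the downstream morphometry statistics (compartment
fractions, group summaries, sexual-dimorphism contrasts, method agreement,
correlation) and ships a reference dataset of ten Ring-necked pheasant
(*Phasianus colchicus*) specimens for worked examples and cross-checks.

## The Fakir estimators

Let a grid of parallel lines in unit direction $e_k$ have transverse spacing
$d$, so each line carries a tributary area $d^2$. If the lines intersect an
object with total intercept length $L_k$ (mm) and cross its boundary $I_k$
times, then

$$\hat V_k = d^2 L_k, \qquad \hat S_k = 2\, d^2 I_k.$$

$\hat V_k$ is unbiased for the volume at *any* orientation (Cavalieri-type
argument). $\hat S_k$ is unbiased only on average over isotropic
orientations: a surface patch with unit normal $n$ is crossed in proportion
to $|\langle n, e_k\rangle|$, whose spherical mean is $1/2$ — hence the
factor 2. A probe with $m$ directions and weights $w_k$ (summing to 1)
reports the convex combinations $\hat V = d^2 \sum_k w_k L_k$ and
$\hat S = 2 d^2 \sum_k w_k I_k$; each grid alone is unbiased, so any convex
weighting is too.

`fakir_estimate()` applies one probe placement (a shared Haar-uniform random
rotation of all grids plus uniform random lattice offsets in $[0,d)^2$);
`fakir_replicate()` repeats it over independent rotations and reports the
mean with a standard error from the between-rotation spread. The replication
SE is assumption-free; no within-grid variance formula is used.

### Orientation variance and the probe hierarchy

For a *planar* object — the worst case — the surface estimator's orientation
factor is $f(n) = \sum_k w_k\, 2|\langle n, e_k\rangle|$, with unit mean
over isotropic normals. Its coefficient of variation is the orientation CV:

* single grid: $\mathrm{CV} = \sqrt{1/3} \approx 0.58$ (closed form from the
  moments of $|\cos\theta|$ on the sphere);
* orthogonal triplet, equal weights:
  $\mathrm{CV} = \sqrt{(1 + 4/\pi)/2.25 - 1} \approx 0.10$;
* seven-fold probe (the 3 cube axes plus the 4 normalized body diagonals):
  $\mathrm{CV} \approx 0.034$ after weight optimization, comfortably below
  0.04.

`planar_cv()` reproduces these by Monte Carlo (isotropic normals from
normalized 3D Gaussians). `optimize_sevenfold_weights()` minimizes the CV
over the one natural free parameter — the total weight $\alpha$ on the
axial grids, shared equally, versus the diagonals — by scalar search on a
fixed Monte-Carlo sample, which makes the objective deterministic given the
seed. At $10^6$ samples the optimum sits near $\alpha \approx 0.41$
(per-grid axial:diagonal weight ratio $\approx 0.94$) with CV
$\approx 0.034$; equal weights are within $10^{-4}$ of that CV, so the
seven-fold geometry itself, not the weighting, does almost all the work.
The estimator default is therefore equal weights, with optimized weights
available via `sevenfold_weighted()`.

Two design readings are worth recording. "Planar object" is operationalized
as the orientation factor of an infinitesimal flat patch (a pure
$|\cos\theta|$ response), not a finite voxelized lamina: this isolates
orientation variance exactly and admits the closed-form oracles above.
And the seven-direction set is fixed as cube axes plus body diagonals — the
canonical 7-direction cube set — because no authoritative listing of the
original direction set was available to us; the choice is a package
decision, checked by its measured CV.

### Antithetic effect and grid staggering

For anisotropic objects the per-grid partial surface estimates
$2 d^2 I_k$ of differently oriented grids are *negatively* correlated across
random rotations (when the object's normal favours one direction it
disfavours the others), so their average has lower variance than any single
grid — the antithetic effect. `antithetic_covariance()` measures the
$m \times m$ covariance of the partials across rotations; on a thin lamina
the off-diagonal sum is strongly negative and the combined variance is an
order of magnitude below the mean single-grid variance.

The grids are also *mutually staggered* ("fakir bed" interleaving): where two
grids share a transverse lattice axis (as the axial grids of the triple and
seven-fold probes do), the second grid is shifted by $d/2$ along it, so line
positions interleave at half spacing and local fluctuations partially
cancel. Diagonal grids share no transverse axis with any other grid, so no
shift applies to them; their offsets are independent. Staggering is on by
default (`staggered = TRUE`) and never affects unbiasedness, only variance.

### Line-mask intersection: numerical choices

Lines are sampled at a step of `min(spacing)/4` (default); entry and exit
points are located where the interpolated occupancy crosses the 0.5
iso-level, refined linearly between consecutive samples. Intervals shorter
than the step are kept when detected; no minimum-length filter exists. The
mask is conceptually padded with background, so objects touching the array
edge still produce exit crossings, and all geometry is computed in physical
millimetres (anisotropic voxels are handled by construction, never by
resampling).

One numerical choice matters enough to spell out. The 0.5 level set of the
*raw* trilinear occupancy of a binary mask is the digitized staircase
boundary: grazing lines cross its voxel-scale bumps several times, and on a
sphere of radius 10 mm at 0.25 mm voxels this inflates the surface estimate
by about 8%. The estimator therefore presmooths the occupancy with a
separable box filter of radius one voxel (`smooth_radius = 1`) before
tracing. The smoothed 0.5 level set tracks the true interface at sub-voxel
accuracy — the level-set shift is of order (kernel variance) x (boundary
curvature), about 0.005 mm for that sphere — bringing the sphere surface
error to +0.3% and the volume error to -0.2%. The flip side: for *coarsely
resolved* objects (feature radius below ~15 voxels) the curvature shift
becomes visible (a 5 mm sphere at 0.5 mm voxels loses ~2% volume), so
resolution should be chosen with the default `spacing <= feature/4`
generator guard in mind, or smoothing disabled (`smooth_radius = 0`) when
measuring axis-aligned synthetic shapes whose sharp faces are exactly
representable.

### What the phantoms do and do not emulate

The generator produces spheres, ellipsoids, laminae, hollow shells
(optionally pierced by cylindrical "foramina"), three-compartment fused
ellipsoid "brains" with prescribed volume fractions (defaults 0.64 / 0.16 /
0.20, the adult means of the bundled dataset; default whole-brain volume
3556 mm^3, their adult grand mean), and CT renderings of bone masks with
seeded Gaussian noise. Voxelization is a centre-point inside-test with no
partial-volume antialiasing — unbiased for volume as spacing shrinks and
exactly what the estimator consumes. Ground truths are closed-form wherever
they exist (sphere, spheroid) and fine midpoint quadrature for triaxial
ellipsoids (the quadrature grid is recorded in the truth object).

Phantoms are smooth, noise-free (masks) and perfectly segmented. Passing
tests on them demonstrates the estimators' statistical properties —
unbiasedness, variance reduction, convergence — but says nothing about
segmentation error, partial-volume effects at real tissue interfaces,
motion or reconstruction artefacts. Those belong to the acquisition side,
which this package does not model.

## Watershed extraction of cavity spaces

`extract_cavity()` chains the CT stages: Otsu (between-class-variance)
thresholding of bone — or a fixed cutoff; morphological closing of the bone
mask with a Euclidean ball (radius in mm, default 2 voxels) to seal
foramina narrower than the ball diameter; a relief; and marker-based
priority-flood watershed from a user-supplied cavity seed against an
exterior marker automatically placed on the full volume border. The cavity
is the cavity-labeled non-bone region.

Design choices, all made where the upstream method description is silent:

* **Relief.** The default is the negated distance-to-bone transform (exact
  anisotropic Euclidean distance, separable lower-envelope algorithm), which
  makes cavity centres deep basin minima and is robust for binary-bone
  contrast; the intensity-gradient relief (mm-aware central differences) is
  available for noisy-intensity use where bone is not cleanly thresholdable.
* **Connectivity.** Flooding uses 6-connectivity by default so the flood
  cannot leak diagonally through a one-voxel bone wall; 26 is a flag.
* **Determinism.** The flood is a strict priority queue ordered by (relief,
  insertion order); marker voxels enter in ascending linear index. Repeat
  runs are bit-identical, and a brute-force reference flood reproduces the
  labels exactly on small instances.
* **Leak detection.** If, after closing, cavity-labeled and exterior-labeled
  non-bone voxels are face-adjacent, the cavity is open to the outside; the
  result is flagged `leaky` rather than silently reporting a meaningless
  volume. A solid object (no cavity) either errors (seed in bone) or comes
  back leaky.

On hollow-shell phantoms (inner radius 8 mm, outer 10 mm, 0.25 mm voxels,
noisy CT) the recovered cavity volume is within 0.1% of the analytic
4/3*pi*8^3, with or without three 1 mm foramina sealed by a 0.75 mm closing
ball. Closing with a ball that fits inside the cavity leaves the cavity
surface untouched in the continuum limit (the opening of the cavity by the
ball is the cavity itself); discretization contributes sub-voxel error only.

## Morphometry statistics and table conventions

`study_table()` holds per-specimen, per-region volume/surface records plus
whole-brain totals. Two conventions were fixed after inspecting the bundled
tables:

* **Stated totals are kept, but fractions use the sum of parts.** The
  published totals are rounded independently of the region values (they
  differ from the region sums by up to 1 mm^3/mm^2, which the constructor
  enforces as a consistency bound). Compartment fractions are computed as
  region / (sum of the specimen's three region values): dividing by the
  separately rounded total would propagate its rounding error into the
  fractions and fails to reproduce one published 2-decimal cell, while the
  sum-of-parts convention reproduces every cell of the bundled 2-dp
  fraction table exactly. Totals-based statistics (group summaries, the
  dimorphism contrast, method agreement) use the stated totals, which is
  what reproduces the published per-sex mean +/- SD rows exactly.
* **Display rounding is half away from zero** at the target table's
  precision; all internal arithmetic is full precision. Sample SDs use the
  n-1 denominator (verified against all four published +/- entries).

The sexual-dimorphism contrast is the percent difference of male versus
female means with a two-sided Welch (unequal-variance) two-sample p-value —
chosen because no test was specified upstream and n = 3 per sex gives a
pooled-variance test no extra credibility. On the bundled adult totals the
male enlargement is +10.2% (volume) and +10.4% (surface); the Welch
p-values are 0.074 and 0.070. A claim of p < 0.05 is therefore *not*
reproduced from the printed per-specimen totals under this test choice
(a one-sided reading, defensible for a directional hypothesis, would give
~0.04); the package reports the number it computes.

`method_agreement()` summarizes signed percent deviations
(comparison - reference)/reference over pairs; on the per-sex brain volumes
(manual MR delineation as reference, Fakir probe as comparison) the mean
deviation is +0.4%, and on the endocranial volumes (manual MR vs CT
watershed) the mean magnitude is ~8% — bone delineation on MR is the weak
point, which is the argument for the CT watershed stage. `pearson_r()` on
all 30 (volume, surface) compartment pairs of the bundled table gives
r = 0.993; a published correlation of 0.997 refers to a "surfaced weighted
mean distance" quantity whose definition we could not pin down, so the
package computes and reports r without asserting that value.

## Problem sizes and runtime

The test suite and the acceptance script were sized to run on one CPU in a
few minutes total: orientation CVs use 10^6 isotropic normals (about a
second each); estimator checks use a radius-10 mm sphere and a 10x10x2 mm
oblate spheroid at 0.25 mm voxels with a seven-fold probe at d = 1 mm and
20 rotations (a few seconds each); the antithetic check uses a 20x20x0.5 mm
lamina, triple probe, 60 rotations; watershed checks use shells of ~0.7M
voxels. Unbiasedness is additionally checked at 200 rotations with a
coarser grid (d = 1.5 mm). All randomness flows from explicit seeds.

## Known limitations

* Surface estimates inherit a small digitization bias (fraction of a
  percent at >=40 voxels per object diameter, percent-level below ~20); the
  presmoothing radius trades bump-crossing inflation against curvature
  shrinkage and is exposed, not hidden.
* The seven-fold direction set and its weighting are package decisions (see
  above), validated against the printed CV hierarchy, not against an
  original implementation.
* The watershed stage assumes bone separates cavity from exterior after
  closing; pathologically wide openings (wider than twice the closing
  radius) correctly come back `leaky` rather than measured.
* Vertical-design stereology (anisotropy-weighted probes), plate/cycloid
  probes, mesh-based surface measurement and MR/CT co-registration are out
  of scope.
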