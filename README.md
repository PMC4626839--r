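# fakir3d

Fakir line-probe stereology and watershed morphometry for 3D volumes.

## What it is for

Comparative brain volumetry needs unbiased volumes and surface areas of
segmented structures — the brain, its major compartments (prosencephalon,
mesencephalon, rhombencephalon) and the endoneurocranial cavity — measured
from MR and micro-CT data. `fakir3d` implements:

* **Fakir probe estimators.** A probe is one or more lattices of parallel
  lines with spacing *d* under a shared random (Haar-uniform) rotation. A
  grid in direction *e_k* with total intercept length *L_k* and boundary
  crossing count *I_k* gives the unbiased partial estimates

      V_k = d^2 L_k        S_k = 2 d^2 I_k

  (the surface estimate is unbiased over isotropic orientation). Probes
  with 1, 3 (orthogonal triplet) or 7 directions (cube axes + body
  diagonals) combine the partials with weights summing to 1. Multi-grid
  probes gain twice: negatively correlated partials (the antithetic
  effect) and mutually staggered lattices cut the variance, and the
  orientation CV for planar (worst-case) objects falls from 0.58 (single)
  to 0.10 (triple) to below 0.04 (seven-fold).
* **Watershed cavity extraction.** Otsu bone thresholding, morphological
  closing that seals foramina, a distance (or gradient) relief, and a
  deterministic marker-based priority-flood watershed recover the
  endocranial space from CT-like volumes, with a `leaky` flag when a
  cavity is open to the exterior.
* **Morphometry statistics.** Compartment fractions, group summaries
  (mean ± n−1 SD), sexual-dimorphism contrasts (percent difference +
  Welch p), method-agreement deviations and Pearson correlation, plus a
  bundled reference dataset of ten Ring-necked pheasant specimens.
* **Phantoms and I/O.** Synthetic spheres, ellipsoids, laminae, hollow
  shells and three-compartment "brains" with analytic ground truth;
  NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`) volumes; CSV
  study tables; JSON provenance.

## Worked example

```r
library(fakir3d)

# a 10 mm sphere at 0.25 mm voxels, seven-fold probe, d = 1 mm
ph  <- phantom_sphere(10, 0.25)
est <- fakir_replicate(ph$mask, direction_set("sevenfold"), d = 1,
                       n_rotations = 20, seed = 1)
est
#> <fakir_estimate> sevenfold probe, d = 1 mm
#>   volume  4181.14 mm^3 (SE 0.57, 20 rotations)
#>   surface 1259.03 mm^2 (SE 0.72)
ph$truth$volume; ph$truth$surface
#> 4188.79 mm^3, 1256.64 mm^2  (analytic 4/3 pi r^3, 4 pi r^2)

# orientation CV of a single-grid probe for planar objects (closed form 0.577)
set.seed(1)
planar_cv(direction_set("single"))
#> <cv_result> single probe: CV = 0.5778 (mean factor 0.9995, n = 1e+06)

# cavity extraction from a noisy CT of a pierced hollow shell
sh  <- phantom_hollow_shell(8, 10, 0.25, holes = data.frame(axis = 1:3, diameter = 1))
ct  <- phantom_ct(sh$mask, 1000, 0, noise_sd = 30, seed = 2)
seg <- extract_cavity(ct, ceiling(dim(ct$intensity) / 2), close_radius = 0.75)
seg
#> <segmentation_result> cavity 2145.38 mm^3 (137304 voxels)
sh$truth$cavity_volume
#> 2144.66 mm^3  (analytic 4/3 pi 8^3; the 1 mm foramina are sealed by closing)

# bundled pheasant morphometry
tabs <- pheasant_tables()
dimorphism_contrast(tabs$compartments, "volume")$percent_difference
#> 10.2  (% male enlargement of adult whole-brain volume; Welch p = 0.074)
method_agreement(c(3335, 3752), c(3383, 3729))  # manual MR vs Fakir volumes
#> 0.4 +/- 1.5 (n = 2)
```

A command-line dispatcher over the same functions ships at
`inst/cli/fakir3d.R` with verbs `phantom`, `measure`, `cv`, `segment-ct`
and `stats` (global flags `--seed`, `--out`, `--log-level`; every output
gets a JSON provenance sidecar).

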