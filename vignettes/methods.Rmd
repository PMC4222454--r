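---
title: "Counting nanoparticles in single cells: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nanoparticles in single cells: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uptake3d)
```

## The measurement problem

Fluorescence microscopy of nanoparticle uptake yields two 3D z-stacks per
cell: a membrane stain delineating the cell and a particle channel in which
every labelled particle — or agglomerate of particles — appears as one
diffraction-limited spot. Two questions have to be answered per cell: *how
many* particles are present, and *where* are they relative to the cell —
internalised, associated with the membrane, or outside.

Counting by spots alone fails because agglomerates image as single spots.
The method implemented here instead counts by *intensity*: if the dye load
per particle is uniform and self-quenching inside agglomerates is
negligible, the integrated fluorescence of an object containing $k$
particles is $k$ times the single-particle intensity $I_1$, so

$$ \hat{k} \;=\; \operatorname{round}\!\left(\frac{I_{\mathrm{obj}}}{I_1}\right), $$

with $I_1$ measured once per particle batch from a calibration sample of
isolated particles deposited on a coverslip and imaged with identical
settings. Objects that pass detection count at least one particle, so
$\hat k$ is clamped at 1.

## Cell reconstruction and the membrane region

The membrane channel is smoothed (Gaussian, `smoothing_sigma_um`, default
0.2 µm — about one camera pixel), binarised with a global Otsu threshold on
the full 3D histogram, hole-filled slice by slice (slice-wise rather than in
3D, so a cell cropped by the top or bottom of the stack still fills), and
reduced to its largest connected component — one cell per analysis.

Because the boundary of a thresholded, diffraction-blurred membrane is
uncertain at the few-hundred-nanometre scale, the classification does not
use a sharp boundary. Instead a *membrane region* of total width
`shell_width_um` (default **1.4 µm**, much wider than the actual bilayer)
is centred on the estimated membrane: everything deeper than $w/2$ inside is
intracellular, everything farther than $w/2$ outside is extracellular, and
the transition zone absorbs all boundary ambiguity. Distances are true
Euclidean distances in micrometres computed by a separable anisotropic
distance transform, so the region has the same physical width along z
(0.25 µm sections) as in the image plane.

Two geometric choices deserve note:

* **Symmetric placement.** The region extends $w/2$ inward and $w/2$
  outward of the boundary. Only the total width is a documented property of
  the method; centring it symmetrically is this package's convention for a
  "transition region between extra- and intracellular space".
* **Boundary pull-back to the stain ridge.** A threshold mask of a blurred
  shell ends on the *outer flank* of the membrane signal — by several
  hundred nanometres along z, where the PSF is widest. `reconstruct_cell()`
  therefore measures the intensity-weighted mean depth of the
  above-threshold membrane signal inside the mask — binned by the axial
  component of the local surface normal, since the flank is deepest where
  the normal points along z — and shifts the boundary inward by that
  depth before centring the shell, so the transition region straddles the
  stained membrane rather than its optical flank.
  `build_regions()` with `boundary_offset_um = 0` gives the uncorrected
  behaviour.

## Spot detection and intensity measurement

The particle channel is background-corrected by a slice-wise median filter
(`median_radius_um`, default 2 µm) whose window excludes pixels more than
3 robust sd above the global background — a sigma-clipped background, so
bright spots cannot inflate their own background estimate. Voxels above
`median + k·MAD` (default `k = 5`) form 3D connected components
(26-connectivity); components smaller than `min_voxels = 4` are discarded as
hot pixels.

Integrated intensity is measured by **fixed-margin aperture photometry**:
each component is dilated by `measure_dilation_um` (default 0.7 µm, voxels
assigned to their nearest object so apertures never overlap), intensities
are summed over the aperture on the *unclipped* residuals, and a local
background level measured in a 0.5 µm annulus around the aperture is
subtracted, scaled by the aperture size. Three systematic errors motivate
this over summing only above-threshold voxels:

1. the fraction of a spot's flux above a fixed threshold grows with its
   brightness, which would make $I_{k}/I_1 > k$ and overcount large
   agglomerates at any realistic noise level — a fixed-size aperture makes
   the captured fraction brightness-independent;
2. zero-clipping residuals rectifies noise and biases aperture sums upward;
3. whatever small local bias survives the median filter multiplies the
   ~10³-voxel aperture — the annulus measures and removes it.

With `measure_dilation_um = 0`, integration reverts to exactly the
above-threshold voxels of each component (useful for the additivity
identity: summed object intensities then equal the total above-threshold
image mass).

## Calibration

`calibrate_single_particle()` runs the same detection pipeline on the
calibration stacks — identical settings matter, because the aperture
capture fraction must cancel in $I_{\mathrm{obj}}/I_1$ — pools the spot
intensities and fits a Gaussian by iteratively trimmed maximum likelihood:
fit mean and sd, discard spots outside ±2.5 sd, refit until stable (at most
10 rounds). The trim removes multi-particle spots, which sit near integer
multiples of the mean — a doublet is ~10 sd away at 10% intensity spread —
without assuming how many there are. `fit_ok` turns `FALSE` when more than
half the spots are trimmed, which signals a sample too agglomerated to
define a unit intensity.

## The synthetic-data generator

Every stage is validated against `generate_cell_stack()`, a forward model of
the imaging regime the tool targets:

* an analytic cell (sphere for oracles; hemisphere-on-coverslip for the
  flat adherent-cell morphology; ellipsoid) whose membrane is rasterised as
  a 0.4 µm optical shell and blurred with the PSF;
* particle objects as voxel-integrated Gaussian spots (lateral σ 0.15 µm,
  axial σ 0.45 µm, approximating a 1.4 NA oil objective), a $k$-particle
  agglomerate being the sum of $k$ independently drawn unit intensities
  (default unit 48090 with 10% CV, in the raw-intensity range typical of
  dye-loaded silica particles);
* anisotropic voxels (0.25 µm sections, 0.11 µm pixels), Poisson photon
  noise, Gaussian read noise, a uniform background and a camera offset,
  digitised to 16-bit integers. The defaults put single-particle peak SNR
  near 13.

Ground-truth positions are sampled uniformly within the requested region
class of the *analytic* geometry, with a guard margin (default 0.4 µm) from
region borders and stack edges, and a minimum spot separation of 4 PSF
sigmas. The margin exists because a region label is only well defined away
from the boundary that the pipeline itself must estimate; the residual
boundary error after the ridge pull-back is ~0.2 µm, safely inside the
margin. Calibration fields place spots on a jittered sparse lattice
(≥ 3 µm pitch) at one focal plane, as on a real coverslip preparation.

What the generator does *not* emulate — and therefore what passing tests do
not certify on real data: spatially varying backgrounds and autofluorescence,
depth-dependent attenuation and PSF aberration, membrane ruffling and
non-convex cell shapes, photobleaching, particle motion during acquisition,
and dye-load variation beyond a Gaussian CV.

## Statistics

Per-cell totals are the unit of analysis. Condition summaries report
mean ± SEM (sample sd over √n; undefined and reported missing for a single
cell). Group comparisons use the classical pooled-variance unpaired
Student's t-test, two-sided, with significance flagged at p < 0.05 (`*`)
and p < 0.01 (`**`); Welch's correction is available behind a flag but is
not the default, matching the named test. Two zero-variance groups with
equal means are reported as t = 0, p = 1. No multiple-testing correction is
applied.

## Numerical choices and degenerate inputs

* Physical coordinates: axis order (z, y, x), voxel centres at
  `index × voxel_size`, origin at the first voxel centre; centroids are
  intensity-weighted and reported in µm.
* Otsu runs on a 256-bin histogram of the full stack; it is exactly
  invariant under positive rescaling of the intensities.
* On a zero-clipped stack more than half the voxels can be exactly zero,
  collapsing the MAD; the noise sd then falls back to the median of the
  positive residuals divided by `qnorm(0.75)` (half-normal argument).
* Region ties at exact distance $w/2$ resolve into the shell, which exists
  precisely to absorb borderline cases.
* An empty detection is a valid result (all-zero totals), not an error; an
  empty membrane channel is an error ("no cell found").
* Counting rounds half-up and clamps at 1; whether sub-unit objects should
  instead be discarded is a judgement call — clamping is this package's
  documented choice, exposed through the recorded per-object intensities.

## Problem sizes used in the validation suite

The test suite regenerates everything from code: spherical-cell geometry at
0.1 µm isotropic voxels (radius 8 µm) for the shell-width check; 20 seeded
cells (radii 5–6.5 µm) with 11–27 single particles each for exact per-region
recovery; 500 agglomerates of k = 1…10 at 5% intensity CV for counting;
100 calibration fields of 200 spots (10% CV, 10% doublets) for the
calibration bias and doublet-rejection rates; 50 randomised geometries for
the partition/monotonicity invariants, with a brute-force distance oracle
on small instances; and a 10⁵-draw permutation oracle for the t-test.
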