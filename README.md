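# uptake3d

Absolute nanoparticle counting and subcellular localisation from
two-channel 3D fluorescence stacks.

## The problem

Quantifying nanoparticle uptake by cells from confocal z-stacks faces two
obstacles: particles agglomerate, so one fluorescent spot may contain many
particles; and "inside the cell" is ill-defined at the scale of a blurred,
thresholded membrane boundary. `uptake3d` implements an intensity-calibrated
counting method for exactly this setting. It is aimed at groups doing
nanoparticle–cell interaction studies (uptake kinetics, dose–response,
particle-size comparisons) on spinning-disk or point-scanning confocal data.

Given a membrane-stain stack and a particle-channel stack for one cell:

1. **Cell reconstruction** — the membrane channel is smoothed, thresholded
   (Otsu), hole-filled and reduced to one 3D cell mask; an anisotropy-aware
   Euclidean distance transform splits space into three regions:
   *intracellular*, a *membrane region* of total width w (default 1.4 µm,
   deliberately much wider than the bilayer, absorbing boundary
   uncertainty), and *extracellular*.
2. **Spot detection** — objects in the particle channel are 3D connected
   components above a robust `median + 5·MAD` threshold; each object's
   intensity is measured by fixed-margin aperture photometry with local
   annulus background correction.
3. **Counting** — an object of integrated intensity *I* contains
   `round(I / I₁)` particles (clamped at ≥ 1), where *I₁* is the mean
   single-particle intensity fitted — Gaussian with iterative ±2.5 sd
   trimming of multi-particle spots — from a coverslip calibration sample
   imaged with identical settings. This assumes uniform dye load per
   particle and negligible self-quenching in agglomerates.
4. **Reporting** — per-object positions (µm), region labels and particle
   numbers; per-cell totals; mean ± SEM summaries and pooled-variance
   unpaired Student's t-tests (p < 0.05 `*`, p < 0.01 `**`) across
   conditions; pseudo-coloured RGB overlays (membrane cyan, intracellular
   red, membrane-associated yellow).

A synthetic-stack generator (`generate_cell_stack()`,
`generate_calibration_field()`, `generate_kinetics_dataset()`) produces
two-channel scenes with full ground truth — analytic cell shapes, PSF-blurred
spots with integer-multiple brightness, Poisson + read noise, anisotropic
voxels — so the entire pipeline is testable without microscope data.

## Worked example

```r
library(uptake3d)

# a synthetic cell: 6 intracellular, 3 membrane, 4 outside particles,
# one object being a 3-particle agglomerate
p <- scenario_params(cell_radius_um = 5, voxel_size = c(0.25, 0.15, 0.15),
                     particles = data.frame(
                       region = c(rep("intra", 6), rep("shell", 3), rep("outside", 4)),
                       k = c(1, 1, 1, 3, 1, 1,  1, 1, 2,  1, 1, 1, 5)),
                     seed = 7)
sim <- generate_cell_stack(p)

res <- quantify_cell(sim$membrane, sim$particles, cal = 48090)
res
#> <cell_uptake_result>
#>   12 object(s): 8 intracellular / 4 membrane-associated / 8 extracellular
#>   particles (total 20)
sim$truth$totals
#> n_intracellular      n_membrane n_extracellular
#>               8               4               8
```

The 13 placed objects are detected as 12 spots (two nearby membrane
singlets merge into one object of intensity ≈ 2·I₁, counted as 2), and the
per-region particle totals match the generator's ground truth exactly.
`as_analysis_report()` + `write_report()` serialise the result to a
per-object CSV and a JSON summary; `write_overlay()` renders the RGB stack.

For file-based work use `run_pipeline()` or the CLI under `inst/cli/`:

```sh
inst/cli/uptake3d calibrate --stacks calib_dir/ --out cal.json
inst/cli/uptake3d quantify --membrane m.tif --particles p.tif \
    --calibration cal.json --out results/
```

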