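# ivmhisto

**In vivo 3D histomorphometry for multiphoton calvarial imaging.**

Intravital two-photon microscopy of the mouse calvaria can follow, in the
same living animal, both the growth of bone and the fate of the skeletal
stem cells that build it: second harmonic generation (SHG) shows the
collagen matrix, calcein blue and tetracycline injected at two timepoints
mark the old and new bone mineralization fronts, and a
`Prx1-creER-EGFP;tdTomato` reporter labels suture stem cells (green) and
their progeny (red).  Turning those z-stacks into numbers — how many
labeled cells are there, how many became osteocytes inside the newly formed
bone, how much bone was apposed — is the job of this package.  It is aimed
at imaging labs that have the stacks and the manually segmented bone fronts
and want reproducible, scriptable quantification.

`ivmhisto` implements:

* **Automatic 3D cell counting** (`detect_seeds()`): standardized contrast
  enhancement (a fixed fraction of saturated voxels per stack),
  moment-preserving ("Moment", Tsai) segmentation of cell areas, a 3D mean
  filter, anisotropic 3D local-maximum detection sized to the cell
  (defaults x = 6, y = 8, z = 10 px), 26-connected labeling of maxima
  clusters, and a cluster filter based on *Tukey's anomaly*: with the mean
  cell-surrounding intensity x̄ modeled as an exponential background,

      Q1 = x̄·ln(4/3),  Q3 = x̄·ln 4,  T = Q3 + 1.5·(Q3 − Q1)
         = x̄·(ln 4 + 1.5·ln 3) ≈ 3.034·x̄,

  and only maxima clusters brighter than `T` become seeds (one seed = one
  cell, placed at the cluster's intensity-weighted centroid).  A "step
  background gating" rule (background mode + signal-level-dependent offset)
  keeps the noise floor out of x̄.
* **3D bone volumetry** (`measure_volumes()`): per-slice areas enclosed
  between the old (calcein blue) and new (tetracycline) front polylines of
  the frontal and parietal bones, and the suture boundary polygon, summed
  over a 50 µm layer and converted to mm³.
* **Cellular dynamics** (`classify_osteocytes()`, `cell_density()`,
  `fractional_change()`): osteocytes inside the new bone
  (boundary-inclusive on the fluorochrome lines), incorporation rate per
  new-bone volume, and the longitudinal normalization
  ΔM = (M_D28 − M_D0)/M_D0 × 100.
* **Validation & statistics** (`counting_accuracy()`,
  `centroid_deviation()`, `ttest_equal_var()`, `summarize_boxplot()`).
* **A synthetic-data generator** (`generate_cell_stack()`,
  `generate_bone_geometry()`, `generate_paired_study()`) producing
  multi-channel stacks with exact ground-truth centroids, analytic
  prism/wedge bone geometries, and paired Day-0/Day-28 study designs, so
  every stage of the pipeline is testable without microscope data.

## Worked example

Simulate a bright (tdTomato-like) region, count it, and validate against
the generator's ground truth:

```r
library(ivmhisto)

scene <- generate_cell_stack(synth_params(profile = "tdtomato",
                                          rng_seed = 101))
scene$truth$count
#> [1] 222

seeds <- detect_seeds(scene$stack, "TDTOMATO")
count_cells(seeds)
#> [1] 222

counting_accuracy(count_cells(seeds), scene$truth$count)
#> [1] 0

dev <- centroid_deviation(seeds, scene$truth, match_radius = 5)
round(dev$mean_abs_dev, 3)
#>     z     y     x
#> 0.038 0.035 0.034
```

The detected count matches the 222 rendered cells exactly (0% counting
error), and the seeds sit within ~0.04 px of the true cell centers on each
axis.  Volumetry against an analytic wedge geometry:

```r
g <- generate_bone_geometry(shape = c(50L, 101L, 220L),
                            gap_frontal_px = c(10, 20),
                            voxel_size = c(1, 1, 1))
rep <- measure_volumes(g$geometry, depth_slices = 50)
c(measured = rep$new_bone_frontal,
  analytic = g$analytic_volumes$new_bone_frontal)
#> measured analytic
#>  7.5e-05  7.5e-05
```

`fractional_change(100, 130)` returns `30` (% change from the Day-0
baseline); `cell_density(10, rep)` divides an osteocyte count by the total
new-bone volume in mm³.

## Command line

A thin CLI over the same functions is installed at
`exec/ivmhisto` inside the installed package:

```sh
ivmhisto simulate --preset tdtomato --seed 7 --out scene/
ivmhisto count    --stack scene/stack.tif --channel TDTOMATO --out seeds.csv
ivmhisto validate --seeds seeds.csv --truth scene/truth.csv --out accuracy.json
ivmhisto morpho   --geometry scene/geometry.json --seeds seeds.csv --out report.json
ivmhisto run      --config pipeline.yaml
```

`run` executes the full per-region pipeline (counting at both timepoints,
volumetry, osteocyte classification, ΔM, group t-tests) from a YAML config
and writes `region_metrics.csv`, `group_stats.json` and a reproducibility
`manifest.json`.

## Geometry file format

Manual bone-front segmentations are consumed as JSON
(`read_geometry()`/`write_geometry()`):

```json
{"voxel_size": [1, 0.781, 0.781], "frame": [512, 512],
 "slices": [{"z": 0, "fronts": {
   "old_front_frontal": [[0, 80], [511, 80]],
   "new_front_frontal": [[0, 100], [511, 100]],
   "suture_boundary": [[0, 100], [511, 100], [511, 412], [0, 412]]}}]}
```

Coordinates are 0-based `(y, x)` voxel indices per z-slice; front labels
are `old_front_frontal`, `new_front_frontal`, `old_front_parietal`,
`new_front_parietal` and `suture_boundary`.
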