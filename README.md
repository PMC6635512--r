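# zymopore

Linking the 3D pore architecture of intact soil cores to the spatial
distribution of extracellular enzyme activity.

Soil pores structure microbial life: medium-sized pores (30–150 µm
radius) supply water and substrate, large biopores (> 180 µm) drain
quickly, and most of the matrix is only reachable by decomposition
products within a short distance of a pore.  `zymopore` implements the
full measurement chain that makes these relationships quantitative on
intact cores, for soil scientists combining X-ray micro-computed
tomography (µCT) with soil zymography:

* **CT segmentation** — 3D spherical median filtering, lateral border
  trimming, a two-Gaussian fit to the 8-bit gray histogram
  (air + liquid vs solid), and the *minimum-error* threshold `t` that
  balances the misclassified tail areas
  `|Σ_{g>t} G₁(g) − Σ_{g<t} G₂(g)|`, which conserves the voxel balance
  between phases.
* **Pore morphometry** — the continuous pore-size distribution by
  maximal inscribed spheres (local thickness, exact Euclidean distance
  transform + sphere propagation), the field's size classes
  (< 30 µm proxied by the solid matrix, 30–150, 150–180, > 180 µm),
  and image/total/sub-resolution porosity accounting
  (`φ_total = 1 − ρ_b/2.6`).
* **Microbial spatial footprint** — the percent of soil matrix strictly
  within 180 µm of the nearest pore with radius ≥ 30 µm, computed from
  an exact EDT (plus an iterated-dilation variant for comparison with
  classical image-toolbox practice).
* **Zymography** — contact masking (MUF stain), standardization of
  enzyme maps to z-scores (affine-invariant), for any of the six
  commonly mapped enzymes.
* **Co-registration** — fusion of 2D enzyme maps with 3D pore data on a
  1-mm grid, selection of pore-class-representative cells by the
  per-core 95th-percentile rule (ties to the larger class), association
  tables (mean z ± s.e.m. per micro-site class) and a within-core
  permutation contrast.
* **Synthetic cores** — a generator of µCT phantoms and paired
  zymograms with known pore geometry, gray model and injected
  enzyme-effect sizes, so every stage is testable against ground truth.

## Worked example

```r
library(zymopore)

# two synthetic cores: sparse 110-um pores at ~2% porosity, enzyme
# effects +1.0 SD over 30-150 um dominated cells, +0.3 SD over matrix
cores <- lapply(1:2, function(i)
  prepare_core(association_study_spec(rng_seed = i,
                                      core_id = paste0("demo-", i),
                                      grid_shape = c(170, 170, 380)),
               slice_indices = 0:4))     # full CT chain + 1-mm cells
sapply(cores, `[[`, "threshold")         # minimum-error gray thresholds
#> [1] 123 123

rec <- study_records(cores, seed = 1)    # 2 cores x 5 slices x 25 cells
sel <- percentile_select(rec)            # 95th-percentile micro-sites
associate(sel)
#>          pore_class     mean_z       sem n_cells n_slices n_cores
#> 2 unresolved_matrix -1.1259232 0.2489176      12        8       2
#> 1           p30_150  0.1326225 0.2749480      12        8       2

permutation_contrast(sel, "p30_150", "unresolved_matrix", seed = 1)[
  c("estimate", "p_value")]
#> $estimate
#> [1] 1.258546
#> $p_value
#> [1] 0.0045
```

The association table is the micro-site summary: cells whose 30–150 µm
pore abundance is in their core's top 5% carry higher standardized
activity (`mean_z`) than the most matrix-dominated cells, and the
permutation contrast estimates that difference in SD units with a
within-core permutation p-value.  The generator injected a 0.7 SD
contrast; at this 24-selected-cell demo scale the estimate is noisy
(s.e. ≈ 0.37).  The shipped validation runs four cores × ten slices ×
twenty zymogram replicates and recovers the contrast within ±0.15 SD.

Lower-level entry points mirror the pipeline stages:
`median_filter_3d()`, `trim_border()`, `fit_two_gaussians()`,
`minimum_error_threshold()`, `segment_volume()`, `local_thickness()`,
`classify_pores()`, `distance_to_qualifying_pores()`,
`footprint_fraction()`, `standardize_zymogram()`, `build_grid()`.
Volumes, label maps and zymograms read/write standard (multi-page)
TIFF; see `read_volume_tiff()`, `write_zymogram()`.

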