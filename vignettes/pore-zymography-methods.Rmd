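---
title: "Methods: from CT pore architecture to enzyme activity micro-sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CT pore architecture to enzyme activity micro-sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zymopore)
```

## The problem

Soil microbial activity is organized at the scale of pores.
Water, substrate and oxygen supply differ between the fine matrix
(pores below the CT resolution limit), medium transmission pores
(tens to ~150 µm radius) and large biopores (> 180 µm), so the same
soil can host very different enzymatic micro-environments millimeters
apart.  `zymopore` implements the image-analysis chain that makes this
association measurable on intact cores:

1. segment X-ray µCT volumes into pore and solid phases,
2. size every pore voxel by its maximal inscribed sphere,
3. compute how much soil matrix lies close to sizeable pores
   (the *microbial spatial footprint*),
4. standardize 2D zymograms of extracellular enzyme activity, and
5. fuse both modalities on a 1-mm grid and compare activity between
   pore-class-representative micro-sites.

Because no public raw dataset accompanies the design this package
targets, a first-class synthetic-core generator provides every
downstream stage with recoverable ground truth; all quantitative claims
in the test suite are made against that ground truth, not against field
data.

## Segmentation model

Moist soil CT histograms are a two-component mixture: a dark mode from
air + liquid filled pores and a bright mode from solid.  We fit

$$h(g) \approx A_1 e^{-(g-\mu_1)^2/2\sigma_1^2} +
           A_2 e^{-(g-\mu_2)^2/2\sigma_2^2}$$

to the 256-bin 8-bit histogram by Levenberg–Marquardt least squares
(`minpack.lm`), with multi-start initialization: the dominant histogram
mode paired with the best-separated secondary mode, with low-tail gray
quantiles (dense cores may hold only a few percent air + liquid, which
hides the void mode from peak detection), and with bulk quantiles as a
fallback.  $\sigma$ is bounded to [0.5, 128] gray levels; 16-bit input
is min–max rescaled to the 8-bit axis first.

The threshold $t$ minimizes the absolute difference between the two
misclassified tail areas,
$\left|\sum_{g>t} G_1(g) - \sum_{g<t} G_2(g)\right|$, evaluated by an
exhaustive scan over the 256 discrete levels (ties toward the lower
level; the level $t$ itself is counted in neither tail, which makes the
symmetric case land exactly at the midpoint).  Balancing the tails
conserves the voxel balance between phases: on synthetic mixtures with
well-separated means the segmented pore fraction tracks the true void
fraction to well under half a percentage point.  Whether tail areas are
compared on the fitted (amplitude-scaled) components or on
unit-area-normalized densities is an option (`scale =` `"fitted"`
(default) or `"density"`); the two differ only when component weights
are very unequal.

A genuinely two-valued histogram cannot constrain $\sigma$; such fits
are flagged degenerate and the threshold falls back to the midpoint of
the two dominant gray levels.  Preprocessing is a spherical 3D median
filter (radius 2 voxels by default).  Border trimming removes a lateral
shell (default 0.5 cm) because wall-contact artifacts are radial;
trimming the axial faces is available behind a flag.

## Pore sizing and classes

The pore size at a voxel is the radius of the largest sphere that fits
in the pore phase and covers that voxel (local thickness).  We compute
an exact Euclidean distance transform (Felzenszwalb–Huttenlocher) of
the pore phase and propagate each candidate sphere: the maximal sphere
centered at $c$ is the open ball of radius $D(c)$, the distance to the
nearest non-pore voxel center.  Radii are kept as exact squared integer
voxel distances internally, which lets the test suite demand
*voxel-for-voxel* equality with a brute-force search that grows every
candidate sphere directly.  Consequences of the convention:

* an isolated pore voxel has radius 1 voxel (29 µm at the default
  resolution) — no radius below half a voxel can occur;
* a digitized sphere of radius $R$ reports $\approx R$ at every voxel
  it covers (the central maximal sphere covers the whole digitization).

Pore voxels are binned into the field's size classes with bounds
(30, 150, 180) µm: `p30_150` (closed at 150), `p150_180`, `p180_plus`.
The gap class `p150_180` is kept explicit so the bins partition the
radius axis, but it is excluded from three-class association analyses
by default.  Pores below 30 µm cannot be imaged at 29-µm voxels; their
prevalence is proxied by the solid-matrix volume fraction
(`unresolved_matrix`), where sub-resolution porosity resides.  A
grayscale-based proxy (mean solid-phase gray) was considered and
rejected for the default because it couples the proxy to scanner
calibration; the abundance proxy uses geometry only.

Porosity accounting: image porosity is the visible pore fraction of
non-excluded voxels; total porosity comes from gravimetric data as
$1 - \rho_b/\rho_s$ with particle density 2.6 g cm⁻³; their
difference is the sub-resolution (< 30 µm) porosity, clipped at zero
and flagged if negative.

## The microbial spatial footprint

The footprint is the share of solid matrix strictly within a reach
distance (default 180 µm, a conservative summary of observed spatial
correlation ranges of microbial colonization and carbon around pores)
of the nearest *qualifying* pore voxel, where qualifying means an
inscribed-sphere radius of at least 30 µm.  The primary implementation
is the exact Euclidean distance transform of the qualifying set with
strict `< reach` counting; a morphological variant
(`dilation_equivalent_footprint()`) reproduces the classical
iterated-dilation procedure (6- or 26-connected, step count recorded in
the output) to quantify how chamfer-style reach differs from the
metric shell.  POM and excluded-border voxels count in neither the
numerator nor the denominator.

**Known discretization limit.**  Distances are measured voxel center to
voxel center.  For pores a few voxels across, the digitized pore is
systematically smaller than its continuous counterpart (a 60-µm-radius
sphere at 29-µm voxels is 33 voxels, effective radius ≈ 58 µm with
directional shortfall to ≈ 50 µm), so the counted shell around such a
pore undershoots the continuous-geometry shell volume by on the order
of 10%; a half-voxel surface correction overshoots by ~3%.  For pores
well above the voxel size the bias vanishes.  The package keeps the
uncorrected center-to-center metric because it is exact with respect to
its own discrete definition (and provably equal to the brute-force
scan); shell-volume comparisons against continuous formulas should be
read with this bias in mind.

## Zymograms

A zymogram is a photograph of a substrate-saturated membrane after
contact with a cut soil face; brighter gray means more fluorophore
released, hence higher activity (an `invert` flag handles
negative-stain inputs).  Operations are enzyme-agnostic; the six mapped
enzymes are metadata.  Membrane contact quality (MUF staining) enters
as a mask; the stain threshold has no instrument-independent default
and is a per-campaign configuration.  Standardization to z-scores uses
the mean and SD of the usable part of the map and is invariant under
positive affine gray transforms, so camera gain and exposure cancel.

In the full pipeline, standardization happens *after* aggregation to
the 1-mm grid (cell means standardized across the whole slice), which
follows the order of operations of the core procedure this package
implements; pixel-scale standardization is exposed as a utility and as
the `standardize = "before"` option of `build_grid()` for sensitivity
analysis.

## Co-registration and micro-site selection

Each cut face is covered by a grid of 1-mm² cells; each cell is paired
with the 1-mm³ block of CT voxels directly below the new surface (the
imaged material on the uncut side), with the enzyme cell at its face
center.  Zymogram pixels are averaged into cells (cells with usable
pixel coverage below a minimum, default 50%, carry no activity value);
CT quantities averaged per cell are the class volume fractions and the
cell footprint fraction.  Lateral registration is configuration
(flips and quarter-turns), not estimated: the synthetic generator emits
perfectly registered pairs so registration error can be injected
deliberately.

Aggregation smooths pore information, so the association analysis
keeps only cells highly representative of one class: per core and
class, cells whose class abundance strictly exceeds the class's 95th
percentile (type-1/inverse-ECDF quantile, so with continuous abundances
exactly ⌊0.05 n⌋ cells exceed it and ties at the threshold drop out).
Cells exceeding several percentiles join the *largest* class
(`p180_plus` > `p150_180` > `p30_150` > `unresolved_matrix`).  Group
summaries (mean z, s.e.m., cell/slice/core counts) come from
`associate()`; inference is a seeded two-sided permutation test that
permutes class labels within cores, a deliberately simple stand-in for
mixed-effects modeling (the record CSVs are designed so external
mixed-model tools can consume them).

## The synthetic generator

`synthetic_spec()` describes a phantom: grid (29-µm voxels by
default), a pore population of spheres and axis-aligned tubes with
known radii (overlaps resolve to the maximum covering radius, matching
the inscribed-sphere definition), POM inclusions rendered with solid
gray statistics, a two-Gaussian gray model (void mean 60, solid mean
160, SDs 12/15 on the 8-bit axis — separation comfortably above the
2·max(σ) fitting precondition), 2-mm slice spacing, and per-class
enzyme effect sizes in SD units.  Each artifact (placement, grayscale,
each zymogram) draws from a documented substream offset of one seed, so
partial regeneration is bit-reproducible.

Slice spacing is *not* required to be an integer multiple of the voxel
size: a physical saw cut at 2 mm does not land on the 29-µm lattice
either, so cut planes map to the nearest CT plane.  (A strict
multiple-of-voxel rule would be unsatisfiable at the package's own
defaults.)

Zymogram activity of a cell is `baseline + effect(dominant class) +
noise`.  A cell counts as matrix-dominated when its visible-pore volume
fraction is below `min_pore_prevalence` (default 1% of the cell):
porosity below that prevalence is, at field realism, indistinguishable
from matrix.  Otherwise the visible class with the largest volume wins,
ties to the larger class.  Zymogram noise has two parts: cell-level
activity noise (default SD 1.0, the unit of the effect sizes) and a
small per-pixel sensor term (default 0.1); neither is calibrated
against a published noise model, because none is available — they are
stated defaults, not measurements.

What the generator does *not* emulate: real aggregate geometry and
pore-network connectivity, beam hardening and reconstruction artifacts,
fluid-phase partitioning inside pores, membrane deformation, or optical
calibration to absolute enzyme kinetics.  Passing tests therefore
demonstrate the correctness of the measurement chain, not the field
conclusions one might draw with it.

### Validation scenarios and problem sizes

Two reference scenarios are built in:

* `scenario_spec()`: a matched-porosity pair — few large (250 µm)
  spheres versus many 30–150 µm (75 µm) spheres — used to show that at
  equal image porosity the fine-pore architecture reaches strictly more
  matrix within 180 µm.  (128³ grids, 10 seeded replicates in the
  acceptance suite.)
* `association_study_spec()`: sparse 110-µm spheres at ~2% image
  porosity on a 238 × 238 × 690 grid (a 7 × 7 grid of 1-mm cells, ten
  2-mm-spaced faces), with injected effects of +1.0 SD (30–150 µm
  dominated cells) and +0.3 SD (matrix cells).  Four such cores with
  twenty replicate zymogram sets recover the injected 0.7 SD contrast
  through the full chain — render, median filter, fit, threshold,
  segment, local thickness, classify, aggregate, select, contrast —
  within ±0.15 SD, with permutation p < 0.01 in ≥ 95% of replicates.
  Note that slice-level standardization divides by the slice SD
  (≈ 1.03 under these conditions), so the recovered contrast
  concentrates slightly below 0.7; this is a property of
  standardization, not an estimator bias.

These grid sizes were chosen as the smallest at which each property is
cleanly expressed: oracle-equivalence checks run on ≤ 48³ volumes where
the brute-force search is exact and affordable; geometry checks use
300³ so the 180-µm shell is small against the domain; the study cores
use the full 7 × 7 × 10-slice layout the analysis design calls for.

## Numerical choices and degenerate inputs

* Threshold scan: exhaustive over 256 levels, ties toward the lower
  level; degenerate fits fall back to the two-value midpoint.
* Quantiles in percentile selection: type 1 (inverse ECDF), which gives
  the exact ⌊(1−q)·n⌋ exceedance property; strict `>` at the threshold.
* Local thickness / EDT: integer squared distances throughout; no
  floating-point comparisons decide coverage.
* Median filter: truncated neighborhoods at the boundary, upper median
  for the (boundary-only) even counts.
* Empty cases are explicit: no pore voxels (warning, empty map), no
  qualifying pores (infinite distance map, footprint 0), no solid
  voxels (footprint undefined), zero-variance zymograms (rejected),
  single-record groups (s.e.m. reported missing).

## Known limitations

* The center-to-center discretization bias for pores near the voxel
  size (see the footprint section).
* The 95th-percentile rule needs enough cells per core; below 20
  records the quantile is flagged unstable.
* The permutation contrast respects core nesting only; enzyme, system
  and depth strata are not modeled.
* POM identification is taken as an external input (a mask), not
  re-derived from grayscale.

## A minimal worked run

```{r example, eval = FALSE}
sp <- association_study_spec(rng_seed = 1,
                             grid_shape = c(170, 170, 380))
core <- prepare_core(sp, slice_indices = 0:4)
rec <- study_records(list(core), seed = 1)
sel <- percentile_select(rec)
associate(sel)
permutation_contrast(sel, "p30_150", "unresolved_matrix", seed = 1)
```
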