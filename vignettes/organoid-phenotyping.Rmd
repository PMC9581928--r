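---
title: "Quantitative phenotyping of retinal organoids: models, parameters, and validation by parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phenotyping of retinal organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaPheno)
```

## What this package measures

Human retinal organoids (HROs) grown from induced pluripotent stem cells
form a laminated neuroepithelium with cone and rod photoreceptors, Müller
glia (MG) and interneurons.  Pathology models built on them are phenotyped
with a recurring set of quantitative readouts, all of which this package
implements:

* **Cell composition** on cross-section ROIs: nuclei are detected on the
  DAPI channel, assigned to a class by marker colocalization, and reported
  as fractions of total cells and as counts per 100 µm of apical surface.
* **Photoreceptor mosaic geometry** on en-face fields: cell segmentation,
  two-type size classification, density, Voronoi neighbour counts and
  neighbour distances, with edge-cell exclusion.
* **Radial lamination**: ten equal apical→basal bins per ROI; the fraction
  of detected cells or above-threshold pixels per bin describes the
  layering of each marker, and a total-variation summary
  (`dyslaminationIndex`) condenses it to one number.
* **Apical boundary, cell extrusion and inner segments**: the outer
  limiting membrane (OLM) proxy is traced per column from the tissue
  channels; marker-positive nuclei strictly apical of it are ectopic
  (extruded) cells; DAPI-negative marker blobs apical of it are
  photoreceptor inner segments (PIS).  Both are normalized to the apical
  arc length measured within the ROI.
* **En-face area fractions**: maximum projection, global mean threshold,
  foreground fraction — the coverage readout for PIS carpets and glial
  seal-like scars.
* **Fovea-versus-periphery assignment** of single cells: per-(donor,
  region, cell type) reference mean expression vectors, per-cell Pearson
  correlation on the gene intersection, and the per-donor correlation
  delta `r(fovea) − r(periphery)`; plus gene-set eigengenes (first
  principal component) and per-gene Z-scores.
* **Cohort statistics** with the organoid as the experimental unit: ROIs
  are averaged within each organoid before any mean, SD, coefficient of
  variation (COV), t test or one-way ANOVA with Tukey's post hoc test.

Real imaging data of this kind has no accessible ground truth, so every
stage is validated by *parameter recovery*: a synthetic-data module renders
images, cohorts and expression matrices from known parameters, and the test
suite checks that the pipeline recovers them.

## Coordinate and unit conventions

Images are matrices with 1-based indices; **row 1 is apical** and rows
increase toward the basal side; columns run along the apical surface.  All
physical quantities are micrometres, converted through the
`pixelSize` of the `ImageStack`.  "Strictly apical" resolves ties
conservatively: a nucleus exactly on the boundary row is *not* ectopic.

## The synthetic generators and what they emulate

### Cross-sections (`generateCrossSection`, `sectionConfig`)

A cross-section ROI emulates a 100-µm-wide strip of organoid epithelium
(default 100 × 120 µm at 0.5 µm/px).  The apical border undulates
sinusoidally (default amplitude 2 µm, wavelength 50 µm, random phase).
Nuclei are placed by hard-core sequential sampling (default 500 nuclei,
minimum centre spacing 2.2 µm, centres snapped to the pixel grid), with
classes drawn from the configured fractions — default 28/25/25/22% for
cone/rod/MG/other, the composition of a healthy cone-rich organoid — and
depths drawn from truncated-normal bands per class (photoreceptors apical,
glia mid-depth, other cells basal).  The density of 500 nuclei over
roughly 100 × 106 µm of tissue is a realistic 2D idealization of a
12-µm cryosection projection while staying clearly below the jamming
limit of hard-core sequential placement; if random retries jam
regardless, placement falls back to the nearest free grid site before
raising the generation error.

Channels: `dapi` (sum of isotropic Gaussians, σ = nucleus radius/2, default
radius 1.5 µm), one near-binary disk channel per marker class, `rcvrn`
(pan-photoreceptor: cone + rod disks plus PIS half-disks) and `glia` (the
tissue slab).  Additive Gaussian noise (default sd 0.02) is applied last.
Extruded cells are rendered 2.5–8 µm apical of the border — far enough
that their DAPI blob does not fuse with the tissue mask, matching the
appearance of nuclei that have fully passed the OLM.  PIS are half-disks
1–3 µm apical of the border whose DAPI footprint is masked to exactly
zero, making them DAPI-negative by construction.

What is *not* emulated: point-spread-function blur, spectral
bleed-through, intensity inhomogeneity, 3D nuclear overlap, and partial
extrusion (nuclei straddling the OLM).  Passing recovery tests therefore
demonstrates correctness of the measurement logic, not robustness to every
imaging artifact of real microscopy.

### En-face mosaics (`generateEnfaceMosaic`, `mosaicConfig`)

Cone/rod mosaics are jittered hexagonal lattices.  Either the lattice
spacing or the target density may be given (for a hexagonal lattice
`density = 2/(√3·spacing²)`).  Two diameter classes emulate the larger
(type 1, cone-like; default 3.2 ± 0.25 µm) and smaller (type 2, rod-like;
default 2.2 ± 0.25 µm) subpopulations; positional jitter is Gaussian.
Rendering is disk-based at 0.25 µm/px.  `segmentMosaic` recovers cells by
mean-threshold plus watershed on the distance map (touching disks are
split), and `voronoiStats` computes the geometry on the detected centres.

### Wholemounts (`generateWholemount`)

Coverage textures are built by rank-thresholding a smoothed Gaussian
random field (default correlation length 3 µm), so the true foreground
fraction equals the request to within one pixel, for every channel and
every seed.  This makes the en-face area-fraction pipeline testable at the
published coverage values (73% PIS carpet, 57% glial scar).

### Cohorts (`generateCohort`)

Organoid structure is modelled hierarchically: latent per-organoid class
fractions are drawn around the base configuration with additive dispersion
`betweenSd`, per-ROI fractions around those with `withinSd`, each clipped
to the simplex and renormalized.  `covToBetweenSd` inverts the first-order
relation between the additive sd and the latent per-class COV so a cohort
can be generated at a stated interorganoid COV.  Note that the *measured*
interorganoid COV of a counted fraction additionally carries the
per-ROI multinomial counting noise (≈ √(p(1−p)/n)/p per ROI); at 500
cells per ROI and two ROIs per organoid this inflates a 5% latent COV to
roughly 7–8% recovered — a property of any counting experiment of that
size, shared by the estimator, not a pipeline defect.

### Expression sets (`generateExpressionSets`)

Reference cells come from 3 donors × 2 regions (fovea, periphery) × 3 cell
types (cone, rod, MG) — 18 groups.  Gene baseline log-means are Normal
(ln-scale, mean ln 5, sd 1); 10% of genes per cell type are markers
(+1.5 ln units); a configurable fraction of genes (default 10%) carries a
region effect of `regionEffectSize` ln units, half up and half down in the
fovea; donors add small per-gene offsets (sd 0.1).  Counts are Poisson,
optionally with a per-cell log-normal size factor.  Query cells have a
known region identity recorded in `colData()$true_region`.

## Parameters that matter, with defaults

| Parameter | Default | Why |
|---|---|---|
| `pixelSizeUm` (sections) | 0.5 µm | typical 20× confocal sampling |
| `nucleusRadiusUm` | 1.5 µm | rendered nuclear scale; σ = radius/2 |
| `minSpacingUm` (placement) | 2.2 µm | hard-core spacing; keeps blobs resolvable |
| `minSeparationUm` (detection) | 1.8 µm | suppression radius; set by requiring ≥95% recall on generator output (measured 99.4%) |
| `minIntensity` (detection) | 0.25 | rejects noise maxima at noise sd 0.02 |
| `colocRadiusUm` | 1.5 µm | one nucleus radius; 50% disk-coverage rule |
| `minComponentUm2` (boundary) | 50 µm² | excludes detached apical components (extruded cells); the largest remaining component is the epithelium |
| `smoothUm` (boundary) | 5 µm | median window over the per-column top profile |
| PIS `minSizeUm2` / `maxNuclearOverlap` | 1 µm² / 0.1 | suppress single-pixel noise; "DAPI-negative" with a small tolerance |
| `minPisSizeUm2` (pipeline) | 2.5 µm² | below any plausible inner segment, above boundary-discretization slivers of nuclear marker disks |
| mosaic `jitterSdUm` | 0.5 µm | mild disorder typical of a healthy mosaic |
| `regionEffectSize` | 1 ln unit | clearly detectable regional signature |

## Numerical choices and degenerate inputs

* **Mean threshold** is the strict global rule `intensity > mean`; a
  constant image yields a valid empty mask with a `constant` provenance
  flag and a warning.
* **Maxima detection** smooths with σ = suppression radius/4, takes
  8-neighbourhood maxima (`>=`, so plateaus yield candidates), and breaks
  ties by intensity, then row-major pixel order — detection is fully
  deterministic.
* **Boundary estimation** interpolates empty columns linearly, then
  median-filters (5 µm) and lightly mean-filters (2 µm) the per-column top
  profile; the mean filter exists because integer-row staircases otherwise
  inflate the polyline arc length on sloped borders.
* **Connected components** use 4-connectivity (the `EBImage::bwlabel`
  convention), asserted against a flood-fill oracle in the tests.
* **Two-type classification** is deterministic 1D two-means with centres
  initialized at the 25th/75th diameter percentiles; identical diameters
  return a single class with a warning.  This is a stand-in for a trained
  label classifier and no equivalence with one is claimed.
* **Voronoi neighbours** are Delaunay-adjacent cells whose shared Voronoi
  edge lies in the field; a cell is an edge cell if its polygon is clipped
  by the field boundary or it was flagged upstream (label touching the
  image border).  Fewer than 3 or collinear points raise a
  degenerate-geometry error.
* **Dyslamination index** is `1 − TV(p, uniform)/0.9`: 1 for a uniform
  profile, 0 for a single-bin profile; permutation-invariant across bins.
  It is a convenience summary layered on the ten-bin profiles, which
  remain the primary readout.
* **Z-scores** use the sample (n−1) standard deviation; a zero-spread
  vector returns zeros with a warning.  The choice of sample vs population
  sd is a documented convention, switchable by trivial post-scaling.
* **Eigengene sign** is fixed to correlate positively with mean gene-set
  expression across samples.  The variance-stabilizing transform expected
  upstream is `log2(x+1)` of normalized counts (accepted stand-in for a
  regularized log transform; the eigengene itself is transform-agnostic).
* **Intraorganoid COV** defaults to the mean of within-organoid COVs; a
  pooled-variance alternative (`intraMethod = "pooled"`) is provided
  because the verbal definition admits both readings.
* **Degenerate group comparisons**: identical groups return statistic 0
  and p = 1; zero within-group variance with different means returns an
  infinite statistic and p = 0, flagged `degenerate = TRUE`.

## Design decisions that were genuinely open

* The published "5 ± 1 µm neighbour distance" could mean first nearest
  neighbour or mean Voronoi-neighbour distance; both are computed
  (`nn_dist_um`, `mean_neighbor_dist_um`) and the Voronoi-neighbour mean
  is used as the headline spacing estimate.
* "Circumference measured within each ROI" is taken as the boundary *arc
  length* (the chord is trivially available from the ROI width).
* The reference expression scale is declared in metadata rather than
  guessed: raw counts are transformed `log10(x+1)` inside
  `buildReferenceVectors`, matching the transform applied to query cells.
* The organoid — never the ROI — is the unit of analysis in every
  statistic, so two ROIs of one organoid never masquerade as replicates.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data at
desk scale: mosaics up to 200 × 200 µm (~1,800 cells), cohorts of 10–20
organoids × 2 ROIs at 300–500 nuclei per ROI, nine wholemount fields per
coverage level, expression sets of 300–500 genes with 15–30 reference
cells per group, 20-seed replicate loops for stochastic claims, and 2,000
simulated null cohorts for the type-I-error check.  These sizes keep each
stochastic estimate's Monte-Carlo error well inside the tolerance it is
checked against.

## Known limitations

* The generators are 2D; true 3D maxima detection and 3D boundary surfaces
  are out of scope (z-stacks are max-projected first).
* Recovery results certify the measurement logic under the generator's
  noise model, not under uncorrected microscopy artifacts (shading,
  bleed-through, section folds).
* The two-type size classifier assumes a bimodal diameter distribution;
  heavily overlapping populations degrade gracefully but are not resolved.
* The interorganoid COV of counted fractions includes counting noise, as
  discussed above; at small per-ROI cell counts it overestimates the
  latent biological COV.
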