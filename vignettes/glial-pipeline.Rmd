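---
title: "Quantifying glial morphology and glucocorticoid receptor localization in 4-channel confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial morphology and glucocorticoid receptor localization in 4-channel confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Microglia (labelled by OX-42, an anti-CD11b/c antibody) and astrocytes
(labelled by GFAP) respond to aging and chronic stress with changes in
morphology and in the subcellular distribution of the glucocorticoid
receptor (GR).  GR shuttles between cytoplasm and nucleus, so a single
fluorescence channel for GR is only interpretable once each punctum is
assigned to a *cell type* and a *compartment*.  gliaquant implements an
automated voxel-level analysis of 4-channel confocal z-stacks — DAPI
(nuclei), OX-42 (microglia), GR, GFAP (astrocytes) — that produces, per
image and then per animal:

* total microglial and astrocytic channel volumes,
* a count of microglial cells (nuclei completely covered by OX-42),
* microglial soma volumes (OX-42 signal within a dilation shell around
  the nucleus),
* the fraction of each nucleus colocalized with GR, binned into
  quartiles (Q4, "highly GR dense", is more than 75% fill),
* image-level non-nuclear GR volume per glial channel,

and finally the group statistics contrasting age (young/aged) and
stress condition (control/stress/recovery): two-way ANOVA on per-animal
means, Mann–Whitney U, Kruskal–Wallis, two-sample Kolmogorov–Smirnov,
Pearson correlations against external covariates, and eCDF tables.

Because real tissue stacks of this kind are not publicly deposited, the
package ships a synthetic scene generator with complete ground truth;
every stage of the pipeline is validated against that truth or against
per-voxel brute-force oracles.

## The analysis chain

### Thresholding

Each channel of each image is reduced to a binary mask by a per-image
intensity threshold.  The default rule is Otsu's between-class-variance
maximization on a 256-bin histogram; per-channel `percentile` and
`fixed` overrides are available through
`pipeline_config(threshold = ...)`, and the threshold actually used is
recorded on every mask and echoed into all result tables.  Binarization
uses a *strict* inequality (`intensity > t`), so fixed-threshold results
are bit-exact and raising a threshold can only shrink a mask.
Thresholds are always computed per image, never pooled across a cohort:
staining intensity varies image to image, and pooling would let a bright
image shift a dim one's mask.  A constant channel (a marker absent from
the scene) yields an all-background mask rather than an error.

### Nucleus segmentation

Nuclei are separated with a marker-controlled 3D watershed on the DAPI
mask:

1. Euclidean distance-to-background transform, computed with the
   *physical* voxel sizes (default 0.2 × 0.2 × 0.5 µm), so the
   anisotropy of confocal stacks does not distort the distance field;
2. Gaussian smoothing of the distance map (`watershed_sigma`, default 1
   voxel) to remove discretization maxima;
3. h-maxima seeds: distance maxima shallower than `watershed_h`
   (default 0.5 µm) are merged into their parent, which controls split
   sensitivity — two nuclei joined by a neck are split when the neck is
   at least `h` shallower than both cores;
4. priority-flood watershed from the seeds over the mask, in order of
   decreasing distance, with 26-connectivity.

26-connectivity is used everywhere in the package.  All object volumes
are raw voxel counts on the acquisition grid — the nucleus retention
window (1000–1500 voxels, inclusive on both ends) is defined in voxels,
not µm³ — with µm³ derivable from the voxel geometry where needed.

### Classification and GR partitioning

A nucleus is called microglial iff **every** nucleus voxel is
OX-42-positive (100% colocalization).  The rule is strict by default; a
relaxation fraction (`overlap_fraction`) exists for sensitivity analysis
and is logged when used.  Astrocytic nuclei are deliberately *not*
analyzed: GFAP labels intermediate filaments and is reliably absent
from parts of the cell body, so GFAP/DAPI colocalization under-detects
astrocyte nuclei; GFAP enters only the channel-volume and non-nuclear
GR measures.

Per microglial cell:

* nuclear GR fraction = |nucleus ∩ GR| / |nucleus| on the binarized GR
  channel, binned right-closed into Q1 [0, 0.25], Q2 (0.25, 0.5],
  Q3 (0.5, 0.75], Q4 (0.75, 1].  The verbal quartile labels
  ("0–25%", "25–50%", …) overlap at their ends, so a convention is
  forced; right-closed bins with Q1 anchored at 0 are used and tested
  on the exact boundary values.
* soma volume = OX-42-positive voxels inside the 3-voxel Euclidean-ball
  dilation of the nucleus.  The ball lives in voxel space (the rule is
  stated in pixels, not micrometres), and the soma mask includes the
  nucleus footprint — the dilation of a set contains the set; an
  `include_nucleus = FALSE` variant exists for sensitivity analysis.

Image-level non-nuclear GR per glial channel is
|GR ∩ glia| − |GR ∩ glia ∩ DAPI|, restricted to glia-overlapping GR so
it can never be negative, and satisfying the exact partition identity
|GR ∩ glia| = nuclear part + non-nuclear part.  Whether the original
subtraction is done per cell or per image is ambiguous in informal
descriptions of such pipelines; both are computed (the per-cell variant
within the soma mask is a column of the cell table) and the image level
is the validated default, because the subtraction formula is naturally
stated in image totals.  GR *foci* (3D puncta with per-focus volume,
centroid and brightness) are an additional descriptive output produced
by an h-maxima/watershed spot detector; colocalization is always
computed on the binarized channel, not on the foci list.

### Per-animal aggregation and statistics

The animal is the unit of analysis.  Every image measure is averaged
over an animal's images; soma volume is averaged over the animal's
microglial cells.  An animal with zero classified microglia yields
missing values (not zeros) for microglial measures — a zero would be a
fabricated observation.

The group tests are standard machinery behind pinned conventions:

* two-way ANOVA (`value ~ age * stress`) with Type II sums of squares by
  default — cohorts are typically mildly unbalanced, and Type II does
  not depend on factor order; Type I/III are selectable.  Terms with
  zero effect SS report F = 0; a perfect fit (zero residual variance)
  is flagged degenerate.  An empty design cell is an explicit error
  naming the cell.
* Mann–Whitney U with the min(Uₓ, Uᵧ) convention; exact p when both
  n ≤ 8 without ties, tie-corrected normal approximation otherwise.
* Kruskal–Wallis H with tie correction (all-tied data gives H = 0).
* Two-sample KS D with the asymptotic p-value.
* Pearson r with the two-sided t-based p; incomplete covariate pairs
  (e.g. spine densities measured in a subset of animals) are dropped
  pairwise.

The "generalized mixed model" sometimes used alongside such ANOVAs is
not part of the validated surface: with one summary row per animal and
no within-animal replication in the statistics stage, a fixed-effects
two-way ANOVA on per-animal means is the defensible analog.

## The synthetic scene generator

`scene_spec()` + `generate_stack()` build a 4-channel stack and a
ground-truth record of every placement, *before* PSF and noise:

* **Nuclei** are ellipsoids, physically round on the anisotropic grid
  (z semi-axis scaled by voxel-size ratio), resampled until the
  voxelized volume lands in `nucleus_volume_range` (default
  1100–1400 voxels, comfortably inside the 1000–1500 retention window).
  Placement enforces a minimum gap (`placement_margin`, default 3
  voxels) and raises an explicit placement-failure error when a scene
  cannot be packed — never silent truncation.
* **Microglia**: OX-42 = soma shell (nucleus dilated by
  `soma_thickness` = 3 voxels, which guarantees the 100%-colocalization
  property the classifier relies on) plus random-walk processes grown
  from the soma with a mild outward drift, until a per-cell target
  process volume (`arbor_volume`, mean 2000 voxels, 15% relative SD) of
  fresh voxels is painted.  Only topology relative to the nucleus
  matters to the pipeline, not dendritic realism.
* **Astrocytes**: GFAP = star-shaped filaments; only a configurable
  fraction of astrocyte nuclei (default 0.2) is fully GFAP-covered,
  deliberately reproducing the GFAP/DAPI colocalization failure mode
  that makes astrocyte nucleus counting unreliable.
* **GR**: a contiguous nuclear blob filling a per-cell fraction (mean
  0.85 for microglia, so most nuclei are Q4, matching the observation
  that nuclear GR is typically either dense or absent) plus Poisson
  cytoplasmic puncta in a perinuclear shell, never intersecting any
  nucleus.
* **Noise model**: Poisson on the signal (scale 0.5) followed by
  additive Gaussian (SD 5 intensity units), the standard confocal
  approximation; **PSF**: anisotropic Gaussian blur (σ = 0.6, 0.6, 0.4
  voxels).  Both are independently switchable, so noise-free runs are
  exact oracles: with both off, binarizing any channel at
  `signal_floor` recovers the true mask voxel for voxel.

The xy pixel pitch and bit depth of the target acquisition are not
constants of nature: 0.2 µm xy and float intensities on a 0–255-like
scale are configuration defaults, documented here, not measurements.

What the generator does **not** emulate: photobleaching, depth-dependent
attenuation, spectral bleed-through, chromatic aberration, or realistic
process branching statistics.  Passing recovery tests therefore show
that the *algorithmic chain* is correct and stable under
Poisson–Gaussian noise and blur — not that it is robust to every
artifact of real tissue imaging.

`cohort_design()` + `generate_cohort()` extend this to the six-group
young/aged × control/stress/recovery design: per-animal seeds are
derived deterministically from the master seed, and per-group
multiplicative effects on process volume, soma shell thickness and
cytoplasmic GR density are injected through the generator and recorded
in the manifest.  The soma multiplier scales the shell *thickness*, so
soma volume responds monotonically but not exactly proportionally.

## Validation sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic
data, at sizes chosen to exercise every code path while staying
desk-scale:

* voxel-exact oracle checks on random 8³–32³ masks (colocalization,
  subset classification, non-nuclear subtraction, soma dilation,
  channel volume);
* segmentation recovery on noise-free stacks of 12 nuclei
  (192 × 192 × 24) and 30 nuclei (256 × 256 × 20): exact count, ≤ 2%
  per-nucleus volume error, and exact agreement of the 1000–1500 filter
  with ground truth;
* classification recovery: 100% without noise/PSF, ≥ 95% with default
  noise on a 20-cell scene;
* effect recovery: a 1.4× aged-vs-young process-volume multiplier in a
  2 × 2 design with 5 animals per cell (10 per age group), one compact
  64 × 64 × 16 three-cell stack per animal, 100 replicates — the
  reduced scene is process-dominated because total microglial channel
  volume is in reality dominated by processes, and that is the measure
  carrying the age effect.  Power of the ANOVA age term and the type-I
  error at multiplier 1.0 are both reported.

Numerical conventions worth knowing: distances in the EDT are exact
squared Euclidean distances (separable lower-envelope algorithm);
watershed flooding breaks priority ties first-in-first-out, so labels
are deterministic; Otsu ties go to the lowest cut; the foci detector
merges intensity maxima closer than `local_max_tolerance` in height
before splitting a component.  TIFF output stores 16-bit samples with
an `intensity_scale` declared in the JSON sidecar; round-trips are
exact on the 16-bit grid.

## Limitations

* The watershed has one global split-sensitivity parameter `h`; nuclei
  fused by a neck shallower than `h` stay merged, and no shape prior is
  applied.
* The strict 100% OX-42 rule makes microglia counts conservative under
  heavy noise; the relaxation fraction trades specificity for
  sensitivity and is deliberately opt-in.
* Astrocyte instance counting is out of scope (see above), as is
  process skeletonization / branching analysis.
* Group statistics assume one summary row per animal; designs with
  systematic within-animal structure would need the mixed-model route
  that is explicitly excluded here.

## A worked example

```{r, eval = FALSE}
library(gliaquant)

design <- cohort_design(
  groups = expand.grid(age = c("young", "aged"),
                       stress = c("control", "stress"),
                       stringsAsFactors = FALSE),
  n_animals_per_group = 5,
  effects = data.frame(age = "aged", stress = c("control", "stress"),
                       arbor = 1.4, soma = 1, gr_density = 1),
  base_spec = scene_spec(stack_shape = c(96, 96, 20), n_microglia = 2,
                         n_astrocytes = 1, n_other_nuclei = 1,
                         arbor_volume = 3000, placement_margin = 2),
  seed = 4)

out <- simulate_and_analyze(design)
out$recovery
subset(out$report$stats, term == "age" & measure == "microglia_volume")
```

The recovery vector reports the classification accuracy against ground
truth and the measured vs. injected aged/young volume ratio; the stats
table carries the ANOVA age term for total microglial volume.
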