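# gliaquant

Automated 3D confocal image analysis of glial morphology and
glucocorticoid receptor (GR) localization.

## What it does, and for whom

Neuroscience labs studying how aging and chronic stress remodel cortical
glia typically acquire 4-channel confocal z-stacks — DAPI (nuclei),
OX-42 (microglia), GR, GFAP (astrocytes) — and need per-cell,
per-compartment quantities, not raw pictures. gliaquant turns such
stacks into per-animal summary statistics and group comparisons:

- **Per-channel noise thresholding** (per image; Otsu by default, with
  percentile/fixed overrides, every threshold logged), binarization with
  a strict `intensity > t` rule.
- **3D watershed nucleus segmentation** on the DAPI mask:
  anisotropy-aware Euclidean distance transform → Gaussian smoothing →
  h-maxima seeds → marker-controlled priority-flood watershed
  (26-connectivity), followed by an inclusive 1000–1500-voxel nucleus
  volume filter.
- **Microglia identification** by complete colocalization: a nucleus is
  microglial iff every nucleus voxel is OX-42-positive.
- **GR partitioning**: per-cell nuclear GR fraction
  f = |nucleus ∩ GR| / |nucleus|, binned into right-closed quartiles
  (Q4 = f > 0.75, "highly GR dense"); image-level non-nuclear GR per
  glial channel as |GR ∩ glia| − |GR ∩ glia ∩ DAPI|, which satisfies the
  exact partition identity |GR ∩ glia| = nuclear + non-nuclear.
- **Soma volumetry**: OX-42 signal inside the 3-voxel Euclidean-ball
  dilation of the nucleus.
- **GR foci detection** (descriptive): 3D puncta with volume, centroid,
  mean/peak brightness.
- **Group statistics** on per-animal means: two-way age × stress ANOVA
  (Type II SS), Mann–Whitney U (min(Uₓ, Uᵧ) convention), Kruskal–Wallis,
  two-sample Kolmogorov–Smirnov, Pearson correlations against external
  covariates (e.g. dendritic spine densities), and eCDF tables.

Because tissue stacks of this kind are rarely shared, the package also
ships a **synthetic scene/cohort generator** with complete ground truth
(nucleus voxel sets, cell types, compartment GR content, injected group
effects), so the entire chain is verifiable end to end. See the methods
vignette (`vignettes/glial-pipeline.Rmd`) for the model, parameter
defaults, and the generator's scope.

## Worked example

Simulate a 2 × 2 cohort (5 animals per cell) with a 1.4× aged-vs-young
microglial process-volume effect injected, run the full pipeline, and
recover the effect:

```r
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
round(out$recovery, 4)
#>   classification_accuracy     mean_volume_rel_error                  n_images
#>                    1.0000                    0.0014                   20.0000
#> measured_aged_young_ratio     true_aged_young_ratio
#>                    1.1709                    1.1701

subset(out$report$stats, term == "age" & measure == "microglia_volume")
#>            measure           test term statistic value         p  n
#> 1 microglia_volume  two_way_anova  age         F 42.06 7.522e-06 20
#> 4 microglia_volume mann_whitney_u  age         U  0.00 1.827e-04 20
#> 5 microglia_volume             ks  age         D  1.00 9.080e-05 20
```

Every one of the 20 simulated cells was classified correctly
(microglia vs. not), measured total microglial volume is within 0.2% of
ground truth, the measured aged/young volume ratio (1.171) matches the
ratio actually realized in the truth (1.170), and the ANOVA age term
picks up the injected effect (F = 42.1, p < 1e-5) while Mann–Whitney
and KS agree.

Real data enter through `read_stack()` (multi-page TIFF + JSON sidecar
with voxel geometry and channel order) plus a manifest CSV mapping
images to animals and groups; `run_pipeline()` then produces the same
tables. A thin command-line front-end is in
`inst/cli/gliaquant.R` (`simulate` / `analyze` / `all` subcommands).

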