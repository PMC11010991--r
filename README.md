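# cnscape

Spatial analysis of segmented single-cell tables from multiplexed
immunofluorescence imaging (CODEX-style) of tumor tissue microarrays. The
package answers the question that drives this class of studies: *which
recurring local cell-composition patterns — cellular neighborhoods — make
up a tumor microenvironment, and do they stratify patient outcome?* It is
written for computational pathology and tumor-immunology groups who have
per-cell marker intensities and coordinates (e.g. HALO or similar exports)
plus patient follow-up, and want the downstream spatial statistics as
reproducible, tested R functions.

## What it computes

Starting from a table with one row per segmented cell (patient id, spot
id, x/y centroid in µm, mean intensities for DAPI, PanCK, CD31, CD3, CD4,
CD8, CD68, CD20):

1. **Phenotype gating** — priority-ordered threshold gating into eight
   types (Tumor, Endothelial, CD8_T, CD4_T, Other_T, Macrophage, B_cell,
   Stroma); DAPI⁻ objects are dropped.
2. **Cellular neighborhoods (CNs)** — for each cell the window of the cell
   plus its 9 nearest neighbors; the windows' cell-type frequency vectors
   are pooled across spots and clustered with mini-batch k-means (k = 10);
   similar clusters are merged (average-linkage on centroid cosine
   distance, or an explicit map) into final CNs; every cell inherits the
   CN of its own window. The CN identity map is the *scaled enrichment
   score*: the z-score across CNs of each type's mean window frequency,

   `E[c, t] = ( m[c, t] − mean_c m[·, t] ) / sd_c m[·, t]`,

   with `m[c, t]` the mean frequency of type `t` in the windows of CN `c`.
3. **Proximity** — per-cell nearest-target distances `d(c, T) = min_{t ∈ T}
   ‖x_c − x_t‖`, per-spot means, CN-stratified distance distributions, and
   the spatial score

   `S(c) = d(c, A) / d(c, B)`

   (default: CD8_T center, A = Tumor, B = CD4_T; spot value = mean of
   defined per-cell ratios), so `S > 1` flags CD8 T cells held nearer CD4
   T cells than the tumor.
4. **Outcome association** — Kaplan–Meier / log-rank on median-split CN
   frequencies and in-CN cell counts, Pearson correlations of CN frequency
   against mean CD8→Tumor / CD8→CD4 distances, and a t-test of the spatial
   score between high/low groups; plus t-tests, paired t-tests and one-way
   ANOVA with Bonferroni-corrected pairwise comparisons as general tools.

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates a TMA
cohort — circular 1.5 mm spots, a contiguous mosaic of six planted
composition archetypes per spot, two-channel log-normal marker emission,
and exponential survival whose hazard rises with the lymphoid-archetype
frequency — giving the package a ground truth to validate against.

## Worked example

```r
library(cnscape)
library(dplyr)

cfg    <- synth_config(n_patients = 8, cells_per_spot = 1000, seed = 42)
cohort <- simulate_cohort(cfg)

cells <- assign_cell_types(cohort$cells)       # gate 8 phenotypes
fit   <- detect_neighborhoods(cells, seed = 42) # windows -> k-means -> merge
glance(fit)
#> # A tibble: 1 × 8
#>   n_cells n_windows window_size k_initial n_final inertia merge_mode      seed
#>     <int>     <int>       <dbl>     <dbl>   <int>   <dbl> <chr>          <dbl>
#> 1    8000      8000          10        10       6    385. auto_threshold    42

evaluate_recovery(fit$cells)                   # vs. planted ground truth
#> # A tibble: 1 × 4
#>     ari n_final n_planted type_accuracy
#>   <dbl>   <int>     <int>         <dbl>
#> 1 0.870       6         6         1.000
```

The ten initial clusters merge into the six planted architectures
(`n_final = 6`); the per-cell CN labels agree with the planted regions at
an adjusted Rand index of 0.87 (residual disagreement sits on region
borders, where 10-cell windows straddle two architectures), and gating
recovers essentially every planted phenotype. The association screen then
links architecture to outcome:

```r
run_association_suite(fit$cells, cohort$survival) |>
  filter(test == "pearson")
#>   analysis                          covariate               statistic p_value
#> 1 cn_frequency_distance_correlation CD8_T to Tumor distance    0.760  0.0285
#> 2 cn_frequency_distance_correlation CD8_T to CD4_T distance   -0.541  0.167
```

Here the lymphoid CN's frequency correlates positively with how far CD8 T
cells sit from tumor cells (r = 0.76) and negatively with their distance
to CD4 T cells — the planted "CD8 T cells held inside the lymphocyte-rich
region" geometry. `autoplot(fit)` draws the enrichment cluster map,
`plot_voronoi(voronoi_cells(fit$cells))` the tissue architecture, and
`plot_km()` the survival curves; `run_pipeline()` executes the whole chain
and writes CSV/GeoJSON artifacts plus a run manifest.

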