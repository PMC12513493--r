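# follicular

Spatial single-cell analysis of lymph-node follicles from multiplexed
immunofluorescence, for immunologists studying follicular T/B-cell
biology in case-control cohorts (for example, follicular helper T-cell
expansion in autoimmune disease).

The package takes per-cell tables (centroid coordinates in µm plus one
mean-fluorescence-intensity column per marker) and carries them to
cohort-level statistics:

* **Phenotyping** — per-batch manual thresholds (`call = MFI > t`),
  per-sample 5-component Gaussian-mixture binning for drift-prone
  markers (BCL6: background / negative / low / medium / high, "high" =
  positive), and a hierarchical gating tree: Tfh = PD-1⁺BCL6⁺ Th,
  Tfh-like = PD-1⁺BCL6⁻ Th, Tfr = FOXP3⁺PD-1⁺BCL6⁺, Tfc = CD8⁺PD-1⁺BCL6⁺,
  B subsets by BCL6/CD21/CD27; broadband-bright artifact removal and
  image-level QC (samples with > 30% Unknown cells excluded, one image
  per individual).
* **Compartments** — follicle / mantle / T-zone assignment from GeoJSON
  polygons (innermost-containing-polygon wins) or from a kernel-density
  surrogate of the CD21/CD20/CD4 staining pattern; primary vs secondary
  (germinal-center) follicle classification.
* **Spatial statistics** — average shortest distance between cell types
  D[A][B] = mean over A cells of the distance to the nearest B cell, and
  a neighbourhood interaction score: for each ordered pair (A, B), the
  mean count of B among the k = 10 nearest neighbours of A cells, tested
  against a within-sample label-permutation null with add-one empirical
  p-values, p = (#{perm ≥ obs} + 1)/(n_perm + 1).
* **Cohort statistics** — densities per mm², proportions, Tfh-to-Tfr and
  follicle-to-mantle ratios, compared across groups with two-sided
  unpaired Wilcoxon rank-sum tests and Benjamini–Hochberg adjustment
  (P_adj) within declared families.
* **Synthetic cohorts** — a generator of TMA-core-like fields (follicle
  disk + mantle annulus + T zone, optional Ki67-rich germinal center,
  log-normal marker mixtures, artifact and Unknown fractions,
  group-effect multipliers) with full ground truth, so every stage is
  testable without restricted imaging data.

## Worked example

Simulate a 8-vs-8 cohort in which the pwMS group has twice the mantle
Tfh density, run the full pipeline against the ground-truth regions, and
compare groups:

```r
library(follicular)
library(dplyr)

cfg <- synthetic_config(group_effects = list(pwMS = list(mantle = list(Tfh = 2))))
cohort <- simulate_cohort(cfg, n_per_group = c(pwMS = 8, control = 8), seed = 42)
config <- default_pipeline_config(cfg, rng_seed = 42)

result <- run_pipeline(cohort$cells, cohort$meta, config,
                       regions = synthetic_regions(cfg),
                       groups = c("pwMS", "control"))
result
#> Follicle pipeline run
#>   samples: 16, cells retained: 56601
#>   seed 42, config 4bff87a9262afc7b544473257d387591
#>   phenotype    in  56601 out  54183 excluded  2418
#>   qc_filter    in  56601 out  56601 excluded     0
#>   regions      in  56601 out  56601 excluded     0

result$comparisons |>
  filter(metric == "density", scope == "mantle") |>
  arrange(p_adj) |>
  select(cell_type, n_g1, n_g2, p, p_adj, direction) |>
  head(5)
#> # A tibble: 5 × 6
#>   cell_type  n_g1  n_g2       p  p_adj direction
#>   <chr>     <int> <int>   <dbl>  <dbl> <chr>
#> 1 Tfh           8     8 0.00109 0.0164 pwMS
#> 2 PD-1- Tfr     8     8 0.0199  0.149  control
#> 3 PD-1- Tc      8     8 0.138   0.610  pwMS
#> 4 Tfc           8     8 0.163   0.610  control
#> 5 PD-1+ Tc      8     8 0.204   0.613  pwMS
```

The run log shows cell conservation per stage (56,601 cells in; 2,418
excluded as artifacts or CD3⁺CD4⁺CD8⁺ triple positives). The injected
mantle Tfh effect is the only discovery at P_adj < 0.05 (higher in pwMS);
all other mantle densities are null and stay non-significant. The
Tfh-to-Tfr ratio per compartment is in `result$ratios`, distance
matrices in `result$distances` (heatmap via
`autoplot(cohort_distance_matrix(result$distances))`), and interaction
scores with permutation p-values in `result$interactions`.
`write_results(result, "out/")` saves tidy CSVs plus a JSON run log;
reruns with the same config and seed are identical.

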