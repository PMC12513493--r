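---
title: "Methods: spatial single-cell analysis of lymphoid follicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of lymphoid follicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `follicular`, the
choices that were genuinely open when it was designed, and what the
synthetic testbed does and does not establish about real tissue.

## The analysis problem

Cyclic multiplexed immunofluorescence of lymph-node follicles yields, after
segmentation, a table with one row per cell: centroid coordinates in
micrometers and a mean fluorescence intensity (MFI) per marker. The
pipeline turns such tables into cohort-level statements about follicular
T- and B-cell subsets:

1. **Marker calling.** Most markers are called positive by a per-batch
   manual threshold (`call = MFI > threshold`, strictly). Thresholds are
   per staining batch because absolute MFIs are not comparable across
   TMAs. A monotone rescaling `x / (x + threshold)` anchors every
   threshold at 0.5 for display and cross-batch work; raw values are kept.
2. **GMM binning.** Markers whose staining varies too much for a fixed
   threshold (BCL6 by default) are binned per sample with a 5-component
   univariate Gaussian mixture on log intensity; components are ranked by
   mean into background / negative / low / medium / high, and only "high"
   counts as positive.
3. **Hierarchical gating.** Boolean rules assign each cell one label:
   lineages first (Th, Treg, Tc, B; CD3+CD4+CD8+ triple positives are
   excluded), then subsets (Tfh: PD-1+BCL6+; Tfh-like: PD-1+BCL6-;
   Tfr: FOXP3+PD-1+BCL6+; Tfc: CD8+PD-1+BCL6+; B subsets by BCL6/CD21/CD27).
   Unmatched cells are Unknown. The label set partitions every input cell,
   so counts are conserved through the pipeline.
4. **Compartments.** Cells are assigned to follicle, mantle or T zone by
   user polygons (GeoJSON) when available; otherwise a reproducible
   surrogate for manual annotation smooths the density of CD20+CD21+,
   CD20+CD21- and CD4+CD20- cells on a grid and takes the arg-max class.
5. **Spatial statistics.** Average shortest distances between types, and a
   k-nearest-neighbour interaction score (mean count of type B among the
   k = 10 nearest cells of each type A cell) against a within-sample
   label-permutation null.
6. **Cohort statistics.** Per-sample densities (cells/mm^2), proportions,
   Tfh-to-Tfr and follicle-to-mantle ratios, compared between groups with
   two-sided unpaired Wilcoxon rank-sum tests and Benjamini-Hochberg (BH)
   adjustment within declared families.

## Key parameters

| parameter | default | unit | why |
|---|---|---|---|
| `thresholds[batch][marker]` | midpoint of the synthetic components | MFI | strict `>`; a cell exactly at threshold is negative |
| `gmm_components` | 5 | -- | background/negative/low/medium/high binning |
| `min_cells_gmm` | 50 | cells | below this a sample's GMM calls are NA (gated Unknown) |
| `k_neighbors` | 10 | cells | neighbourhood size for interaction scores |
| `n_permutations` | 1000 | -- | resolution of the empirical p (1/1001 at best) |
| `unknown_frac_max` | 0.30 | fraction | image QC; strictly greater is excluded |
| `artifact_quantile` / `artifact_channel_frac` | 0.95 / 0.80 | -- | broadband-bright artifact rule |
| `auto_annotate` bandwidth / grid | 30 / 10 | µm | bracket typical cell spacing; bandwidth < mantle width |
| `classify_follicle` Ki67 fraction / cluster | 0.10 / 20 cells at 50 µm | -- | germinal-center call; package defaults, not published cut-offs |

Coordinates are continuous micrometers (origin lower-left, y up); all
distances are Euclidean in µm; areas are mm^2.

## Design choices

**Log, not log1p, for GMM binning.** Binning on `log(x)` (zeros floored at
the smallest positive observed value) makes bin assignments *exactly*
equivariant under positive rescaling of the raw intensities, because a
gain becomes a translation and every step of the fit - quantile, k-means
and dynamic-programming initialisations, EM updates, ranking - is
translation-equivariant. A `log1p` transform would tie results to the
arbitrary intensity unit and make this invariance only approximate.

**Multi-start EM.** A single hierarchically-initialised EM fit was
observed to strand rare components: on unequal-weight mixtures it can
split the dominant low component and absorb a small middle one, at a
clearly lower likelihood than the correct solution. `fit_gmm_bins()`
therefore runs EM from a quantile-anchored partition, a mass-guarded
largest-gaps partition, the SSE-optimal one-dimensional k-means partition
(dynamic programming, subsampled to 1000 order statistics for large
samples), and 10 seeded random k-means starts, keeping the best
log-likelihood. Components with weight below 1e-3 or coincident means
(within 1e-6) are merged upward so the bin partition stays total and
"high" is always the top surviving component.

**Permutation p-values.** The interaction test reports add-one empirical
p-values, `p_enrich = (#{perm >= obs} + 1) / (n_perm + 1)` and the
depletion analogue: these are the inferential quantities. The legacy
difference score (observed minus permuted mean, divided by the number of
permutations) is carried alongside for comparability with prior
neighbourhood analyses, but it is not a probability. Permutations shuffle
phenotype labels over fixed positions within a sample; compartment labels
stay with positions. Compartment-restricted scores filter the focal cells
only - neighbourhoods at compartment borders are physically real, so
neighbours may be any cell.

**Gating precedence.** The PD-1 branch is evaluated before the ICOS
branch, so "ICOS+ Th" requires PD-1- and the Th subsets stay disjoint
(disjointness is required for proportion arithmetic). ICOS is
unconstrained for the Tfh call, and BCL6 is unconstrained for "ICOS+ Th";
whether that class should exclude BCL6+ cells is genuinely open, and the
default tree leaves BCL6 free there.

**Denominators and ratios.** Proportions default to all phenotyped
(non-Unknown, non-Excluded) cells in the scope; a parent-lineage
denominator is available. Because Unknown is excluded from the
denominator, both the proportion and the density basis of the
follicle-to-mantle ratio are invariant to the Unknown load of a
compartment. Zero-denominator samples are excluded from the affected
comparison and counted in the report, never imputed: pseudocounts would
silently bias small compartments.

**BH families.** The default analysis adjusts within one
figure-panel-like family (metric x scope); the family id is recorded in
every output row so the adjustment universe is explicit, and a different
family can be declared through `compare_groups(family = )`.

**Wilcoxon ties.** Exact p-values when both groups have at most 25
samples and there are no ties; otherwise the normal approximation with
continuity and tie correction.

## The synthetic testbed

`synthetic_config()` emulates a 1.5 mm TMA core: a 250 µm-radius follicle
disk, a 60 µm mantle annulus, the remaining T zone, and optionally a
120 µm Ki67-rich germinal-center disk. Within each compartment every cell
type is a homogeneous Poisson process - complete spatial randomness is
exactly the null of the permutation test, so the generator doubles as a
type-I-error testbed, while the GC disk provides a known enrichment
signal. Marker intensities are log-normal with separate negative and
positive components; BCL6 comes from the 5-component mixture with
components spaced 5 log-sd apart; artifacts are broadband-bright in every
channel (4% of cells, matching the artifact rate reported for this kind
of data); 5% of cells are lineage-marker-dim and should gate Unknown.

Two generator defaults deserve justification:

* **Marker separation 6 log-sd** between negative and positive components
  of thresholded markers. At 5 log-sd the per-marker miscall rate at the
  midpoint threshold is about 0.6%; a gate inspects 5-7 markers, which
  compounds to roughly 4% per cell and makes a 98% phenotype-recovery
  standard unreachable by construction. At 6 log-sd the per-marker rate
  is 0.14% and cell-level recovery is about 99%. The BCL6 mixture keeps
  5 log-sd spacing, which is the regime the binning recovery standard is
  stated for.
* **Densities** are desk-scale placeholders (about 3-4 thousand cells per
  field, follicles packed with B cells, mantle dominated by naive/memory
  B, T zone by Th/Tc) chosen once for plausibility; no published
  per-subset densities exist to copy, and they are config-exposed, not
  hard-coded.

What passing the synthetic checks does **not** show about real data: the
generator has no cell-cell attraction or exclusion beyond the GC disk, no
segmentation error or marker spillover beyond the artifact fraction, no
batch drift (thresholds are exactly calibrated), and lognormal marginals
with a common shape. Real tissue violates all of these to some degree;
the synthetic results validate the machinery, not the biology.

**Effect-recovery convention.** The end-to-end recovery check (doubled
mantle Tfh density, 30 vs 30 samples) is evaluated on the density
(per-mm^2) metric with ground-truth region polygons. Under the proportion
metric a doubled type mechanically depresses every other type's
proportion in that compartment, so "unaffected" types would not be null;
density leaves them exactly null and makes the false-positive clause
meaningful.

## Numerical details and degenerate inputs

* k-nearest-neighbour and nearest-distance computations are exhaustive
  (C++), with distance ties broken by lower index; results are
  deterministic and match an all-pairs oracle exactly.
* All stochastic stages derive child seeds per (stage, sample) from one
  master seed; a rerun with the same config and seed is identical, and
  derived seeds stay below 2^31.
* Degenerate inputs error loudly rather than guess: all-equal intensities
  for a GMM fit, fields with fewer than k+1 cells, polygons that are
  unlabelled, degenerate or self-intersecting, cohorts with fewer than
  two samples in a group, expected synthetic fields below 10 cells.
* A field with no CD20+ cells cannot be annotated and is labelled all
  T zone with a warning; a follicle without B cells gets follicle class
  "unknown" with a warning.

## Problem sizes used in validation

The shipped checks run at: 50 random fields (<= 500 points) for the
oracle equivalence; 500 CSR fields of 300 cells (k = 10, 200
permutations) for calibration; ten 5000-cell mixtures for binning
recovery; six default fields (~20k cells) for gating recovery; four
fields for region-surrogate agreement; and twenty 30-vs-30 cohorts for
end-to-end effect recovery. These sizes were chosen so the whole
validation runs comfortably on a laptop while keeping Monte-Carlo error
well inside the stated margins.

## Known limitations

* The density surrogate for compartment annotation assumes one central
  follicle per field (as in follicle-centred TMA crops); multi-follicle
  fields need manual polygons.
* CXCR5 is deliberately absent from the default panel and gates.
* The germinal-center call uses explicit numeric defaults where the
  original workflow relied on visual staining patterns; the defaults are
  reproducible but not validated against expert annotation.
* Covariates (age, site, malignancy) are handled by cohort matching
  upstream, not by regression; there is no modelling interface for them.
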