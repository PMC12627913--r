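---
title: "Comparing eDNA metabarcoding communities across sampling stations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing eDNA metabarcoding communities across sampling stations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednacomp)
```

## The problem

Environmental DNA (eDNA) metabarcoding yields feature tables — read counts
of amplicon sequence variants (ASVs) or species per water sample — bound to
geographic sampling points. `ednacomp` takes such a table (a two-sheet
Read/Location workbook or its CSV dialect), cleans it with the standard
filtering rules of the field, and compares community composition between
sampling points: pairwise dissimilarities, nonmetric multidimensional
scaling (nMDS), hierarchical clustering, one-way PERMANOVA, and tests of
hypothesized biogeographic boundary lines. It targets desk-scale analyses:
tens of stations, a few depth levels per station, and up to a few thousand
features.

A *sampling point* is one water sample (usually a station × depth
combination); a *station* groups the depth points collected at one
location. All analyses can run at either resolution
(`stations_aggregate()` sums counts over a station's depths, so the
aggregated presence set is the union of the member presence sets — chosen
because detection-at-station is the natural union semantics for
presence/absence comparisons).

## Filtering model

Filters are applied in a fixed, logged order, mirroring the usual
processing sequence (read-level cleaning first, then sample-level
exclusions, then analysis-time criteria):

1. `remove_low_counts(t = 3)` — every cell with `1 ≤ count ≤ t` is zeroed.
   The default removes singletons, doubletons and tripletons per sample,
   the common guard against index-hopping and PCR/sequencing artifacts.
2. `remove_control_features()` — every feature with reads in any negative
   control is treated as a contaminant and dropped everywhere, then the
   control points themselves are dropped.
3. `exclude_features_by_name()` — consumes an externally prepared exclusion
   list (e.g., non-target or freshwater taxa); this package performs no
   taxonomic lookups itself.
4. `subset_points()` — drops points or whole stations (e.g., stations on a
   current axis believed to transport DNA across a boundary).
5. `prevalence_filter(k = 1)` — keeps features detected at ≥ k points; the
   default keeps everything detected, while `k = 5` is a typical choice to
   exclude rarely detected features from ordination.

Each step returns a `FilterReport` row (features removed, points removed,
cells zeroed) and the pipeline report must reconcile exactly with the
before/after dimensions — this is asserted by the test suite. Features
reduced to all-zero rows are dropped just before distance computation; an
all-zero *point* is an error, because a dissimilarity between empty
samples is undefined.

## Dissimilarities

Two measures are implemented from their formulas:

* **Jaccard distance** `1 − |A∩B|/|A∪B|` on detection sets. The table is
  binarized first; the count-derived ("quantitative Jaccard") variant some
  ecology software computes from Bray–Curtis is deliberately **not** used,
  because results differ. Presence/absence is the appropriate signal when
  detection, not abundance, is reliable (typical for fish eDNA).
* **Bray–Curtis dissimilarity** `Σ|x−y| / Σ(x+y)` on raw counts, with an
  optional per-point relative-abundance normalization (off by default: the
  raw ASV table is the stated input, and no normalization is assumed on
  the user's behalf).

Double zeros are ignored by both measures, as the formulas imply.
Expected richness under rarefaction uses the analytic hypergeometric form
`E[S(n)] = Σ_i (1 − C(N−N_i, n)/C(N, n))`, exact for sampling without
replacement, to judge read-depth sufficiency before comparison.

## Ordination

`nmds()` is built from first principles:

* **Monotone regression** by weighted pool-adjacent-violators (PAVA).
  Ties in the dissimilarities follow Kruskal's *primary* approach: tied
  values impose no order constraint (within a tie block the configuration
  distances are taken in ascending order), which keeps PAVA blocks simple.
* **Stress-1** `sqrt(Σ(d̂−θ)² / Σd̂²)`, where `d̂` are configuration
  distances and `θ` their monotone fit in dissimilarity-rank order.
* **Optimization** by iterative majorization (the Guttman transform with
  disparities) rather than raw gradient descent. Because stress-1 has a
  configuration-dependent denominator, a plain majorization step is not
  guaranteed to lower it; each update is therefore accepted only if
  stress-1 decreases, with step halving toward the Guttman update
  otherwise. This makes the per-iteration stress trace nonincreasing *by
  construction*, a contract the test suite asserts for every start.
* **Starts**: one start initialized from classical scaling (PCoA on the
  double-centered squared-distance matrix, negative-eigenvalue axes
  dropped) plus seeded random starts; defaults `k = 2`, `n_starts = 20`,
  500 iterations, tolerance `1e-7`. Convergence is declared when at least
  two starts agree to a Procrustes RMSE below `1e-4`. The returned
  configuration is centered and rotated to its principal axes.

Unlike some ordination wrappers, no automatic data transformation
(Wisconsin standardization, square-root, autotransform) is applied: the
dissimilarity is computed on exactly the filtered table the user selected.
Users comparing against wrappers with autotransforms should expect
different configurations for abundance-based distances.

All randomness flows from a single user-visible seed; with equal seeds the
entire result (coordinates included) is bit-identical.

## PERMANOVA

One-way, single-factor only — the use cases are two-sided boundary labels
and depth levels. The pseudo-F uses the distance-based decomposition
`SS_total = (1/N)Σ_{i<j} d²`, `SS_within = Σ_g (1/n_g)Σ_{i<j∈g} d²`,
`F = (SS_among/(a−1)) / (SS_within/(N−a))`. Permutations are of whole
sampling points, unrestricted (depth replicates are not treated as
exchangeability blocks, since no blocking structure is assumed). When the
number of distinct label arrangements is ≤ 10,000 they are enumerated
exhaustively and the exact tail proportion is reported; otherwise the
sampled estimator `p = (1 + #{F* ≥ F})/(1 + n_perm)` is used, which never
returns zero. Perfect separation (`SS_within = 0`) is reported as
infinite F rather than an error.

## Boundary tests

A boundary hypothesis is a named west→east polyline with strictly
increasing longitudes; a point is "north" when its latitude exceeds the
linearly interpolated boundary latitude at its longitude
(nearest-endpoint latitude outside the vertex span). This zonal-polyline
model is adequate for roughly east–west dividing lines; full polygons or
great-circle segments are out of scope. Points exactly on the line are
assigned north deterministically, flagged, and warned about. The test
reports two p-values: `p1` over all stations and `p2` after removing a
user-supplied exclusion set (e.g., stations on a current axis); with an
empty exclusion set the two runs are identical by construction.

## Clustering, heatmap, report

Agglomerative clustering uses Lance–Williams updates for single, complete
and average linkage; complete is the default (matching the default of the
standard clustering function in R). Ties merge the pair containing the
earliest points in point-ID order, so results are deterministic. Trees
serialize to newick with nodes at half their merge height, making tree
path lengths equal cophenetic distances. The heatmap is the binarized
table with columns in dendrogram leaf order and rows by descending
prevalence. The report writes the sections in a fixed order — sampling
site map, detection depth, heatmap, nMDS, cluster, species list,
dependencies — with every numeric result also emitted as CSV/JSON/GeoJSON
next to the HTML, and no timestamps, so re-rendering a bundle is
byte-reproducible.

## The synthetic-data generator

`generate_dataset()` emulates the structures the analyses are designed to
detect, with an occupancy-then-abundance (hurdle) model: detection of
feature *f* at point *s* is Bernoulli with
`logit p = logit(baseline) + region_effect·[south & f regional] +
depth_effect·depth_index·[f depth-affected]`, thinned by a per-dataset
batch detection rate; counts given detection are `1 + NegBin(mean,
dispersion)`. Detection carries the regional signal because the Jaccard
path treats presence as the signal; abundance only matters for
Bray–Curtis. Stations sit on a west–east transect straddling a zonal
boundary at 30° N, alternating sides with seeded jitter. Defaults (20
stations, depths 10/50/100/150 m, 200 features, baseline occupancy 0.25,
negative-binomial mean 50 and dispersion 0.8, affected feature fraction
0.3) are fixed once as plausible desk-scale cruise conditions.

What the generator does **not** emulate: oceanographic transport,
spatially autocorrelated communities, sequence-level error, compositional
(library-size) effects, or taxonomic structure. Passing tests therefore
demonstrate correctness of the algorithms and calibration under an
idealized exchangeable null — not robustness to every property of real
cruise data.

Simulation study sizes used by the tests and the acceptance script were
fixed in advance as desk-scale choices: the null calibration uses 500
replicates of 12 stations × 60 features with 199 permutations (the
package's own analysis of its false-positive rate), and the power check
uses the strong-effect condition (log-odds 2.0, 20 stations, 200
features).

## Numerical choices and degenerate inputs

* Counts must be nonnegative integers; blank Read cells are zero;
  fractional counts are an error, not a warning.
* Longitudes are normalized into [−180, 180]; latitudes outside
  [−90, 90] are errors.
* Jaccard/Bray–Curtis on two all-zero vectors is undefined and raised as
  an error naming the offending points.
* A distance matrix with all equal off-diagonal entries is flagged as
  degenerate by `nmds()` (warning, not an error): any configuration is
  rank-concordant.
* A configuration with coincident points has undefined stress (zero
  denominator) and is rejected.
* PAVA comparisons use strict `>` on block means, so already-monotone
  input is returned unchanged and the fit is idempotent.

## Limitations

* Only one-way PERMANOVA; no strata, no multi-factor designs, no
  dispersion (PERMDISP) companion test — a significant result can reflect
  location or dispersion differences.
* Boundary geometry is a zonal polyline classifying by latitude.
* Species-name matching is normalized exact matching (case, whitespace,
  underscores); no fuzzy matching or synonym resolution.
* No phylogenetic (UniFrac-type) distances and no richness estimators
  beyond analytic rarefaction.
* Maps are GeoJSON plus a simple equirectangular scatter; cartographic
  rendering is out of scope.
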