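# mpsprofiler

Unsupervised profiling of invasive vs non-invasive breast cancer phenotypes
from microphysiological-system (MPS) marker panels.

Engineered 3D breast in vitro models expose cells to controlled
tumor-microenvironment conditions — hydrogel stiffness and composition,
environmental pH, and perfusion — and read out a 16-marker panel per
condition: Alamar-blue proliferation over time, breast cancer stem-cell
markers (CD44, CD24, CD44v6, ALDH as MFI and percent positive), and EMT
markers (Vimentin, E-cadherin). With 12 microenvironments × 2 cell lines
(an invasive MDA-MB-231-like and a non-invasive MCF-7-like phenotype), the
resulting tables are high-dimensional relative to their size, and the
question this package answers is: **which markers, under which
microenvironment conditions, are actually needed to tell the invasive
phenotype apart?**

## The method

For records \(x_i \in \mathbb{R}^{16}\) with phenotype labels, the pipeline
runs, per microenvironment condition level (pH, perfusion, hydrogel class,
gelatin content, alginate content — 12 levels):

1. **Blind clustering.** k-means with \(K = 2\) (Lloyd iterations: nearest
   centroid assignment with lowest-index tie-breaking, centroid update, stop
   on stable assignments; 20 distance-weighted restarts, best SSE wins) on
   the standardized marker matrix, scored by the silhouette index
   \(s_i = (b_i - a_i)/\max(a_i, b_i)\) with \(s_i = 0\) for singleton
   clusters, and compared to the true labels through an accuracy-maximizing
   cluster-to-label alignment (confusion matrix, invasive = positive).
2. **Feature ranking.** Mutual information \(I(x^j; y)\) in nats between
   each marker and the phenotype label (nearest-neighbor estimator for
   continuous features vs a discrete label; equal-frequency binned plug-in
   estimator as a cross-check), retaining markers with \(I > 0.65\) —
   just below the balanced-binary ceiling \(\ln 2 \approx 0.693\), i.e.
   only near-perfectly discriminative markers survive.
3. **Re-clustering validation.** k-means again on the retained markers only;
   silhouette and confusion matrix are recomputed to verify that the reduced
   panel still (indeed, better) separates the phenotypes.
4. **Aggregation.** Per-level MI scores are summed across all 12 levels into
   a combined feature score ranking the markers overall.

Within a single cell line, the package also asks how many distinct
environment-driven behaviours exist: silhouette-guided selection of the
number of k-means clusters by the *least-drop rule* (smallest k whose score
is within epsilon of the best), plus greedy silhouette-guided backward
feature elimination. Pearson correlation matrices of markers against the
numerically encoded microenvironment features give the complementary
bird's-eye view.

A seeded synthetic generator (`synthetic_config()` / `generate_markers()`)
emulates the full study design — 2 cell lines × 12 environments ×
replicates, with planted high/moderate/low marker-importance tiers and two
environment-driven regimes — so every stage is testable without the original
experimental data.

## Worked example

```r
library(mpsprofiler)

tbl <- synthetic_config(seed = 42) |>
  generate_markers() |>
  normalize_proliferation()

profile_condition(tbl, "pH", "6.5", seed = 42)
#> condition profile pH = 6.5 (24 records)
#>   silhouette pre = 0.444, post = 0.703; retained 6 marker(s)
```

Feature reduction sharpened the clustering (silhouette 0.44 → 0.70) and the
retained markers recover the phenotypes exactly:

```r
p <- profile_condition(tbl, "pH", "6.5", seed = 42)
p$confusion_post
#> confusion (invasive = positive, swap mapping):
#>   tp = 12  fp = 0
#>   fn = 0  tn = 12  accuracy = 1.000
```

Aggregating over all 12 condition levels ranks the mesenchymal/CD44-family
markers on top, with proliferation and ALDH+ at the bottom:

```r
profiles <- profile_all_conditions(tbl, seed = 42)
head(aggregate_importance(profiles), 6)
#> # A tibble: 6 × 5
#>   marker           combined_score mean_score times_retained  rank
#>   <chr>                     <dbl>      <dbl>          <int> <int>
#> 1 vimentin_pos_pct           8.44      0.704             12     1
#> 2 cd44v6_pos_pct             8.42      0.702             12     2
#> 3 cd44_pos_pct               8.24      0.687             11     3
#> 4 cd44v6_mfi                 8.16      0.680             10     4
#> 5 cd44_mfi                   7.78      0.648              5     5
#> 6 vimentin_mfi               6.93      0.578              3     6
```

Within one cell line, the least-drop rule finds the two planted
environment-driven regimes:

```r
intraphenotype_behaviors(tbl, "invasive", seed = 42)$k
#> [1] 2
```

`autoplot()` methods render the correlation heatmap, per-level ranking bars
and the aggregate importance bar chart; `tidy()`/`glance()` turn every
result into a tibble. `run_profiling_report()` executes all stages and
writes a seed-stamped JSON report plus tidy CSVs that reproduce
byte-for-byte under the same seed.

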