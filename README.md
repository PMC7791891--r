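# immunoseg

Quantification tools for multi-class immune-cell **instance segmentation**
of multiplexed immunofluorescence tissue images — the setting where each
1024 x 1024 confocal field of (for example) a lupus nephritis biopsy
contains a few dozen cells of up to five phenotypes: CD3+CD4+ T cells,
CD3+CD4- T cells, myeloid dendritic cells (mDC), plasmacytoid dendritic
cells (pDC), and B cells. The package is for image-analysis and
computational-pathology groups who need to (a) score a segmentation
model's predictions against manual ground truth at the cell level, (b)
turn segmentations into physical-unit cell features, (c) compare those
features across tissue-preparation protocols, and (d) do all of this
reproducibly without access to clinical images, via a synthetic tissue
simulator with a controllable error model.

## What it computes

**Cell-matched evaluation.** Predictions with confidence > 0.3 are matched
one-to-one to ground-truth cells of the same class when the pixel
intersection-over-union J(A, B) = |A ∩ B| / |A ∪ B| is at least 0.25. The
assignment maximizes the number of pairs (ties broken by total IOU, solved
as maximum-weight bipartite matching), making the result order-independent
and verifiable against exhaustive enumeration. Pooling counts over frames
gives per-class

    sensitivity = tp / (tp + fn)        "specificity" = tp / (tp + fp)

(the latter is the positive predictive value: true negatives do not exist
for instance detection; every output records this definition) plus
per-cell IOU mean ± SD, and overall rows under both cell-weighted and
class-mean averaging.

**Morphometry and proximity.** Per cell: area (um^2, pixel-count based),
perimeter (um, smoothed marching-squares contour), equivalent diameter
sqrt(4 * area / pi), centroid, border flag. Per T cell: minimum distance
to the nearest dendritic cell (B cells are never targets), centroid or
boundary mode.

**Cohort statistics.** Two-sample Kolmogorov-Smirnov tests, percent change
of means (positive = reduction relative to the reference cohort),
cell-census tables (cells/image, class percentages at printed precision
with round-half-up), and seeded largest-remainder train/validation/test
splits.

**Simulation.** `generate_truth()` draws clustered cohorts with per-class
log-normal cell sizes and panel-consistent class mixtures;
`apply_fixation_shrinkage()` models formalin-fixation contraction as a
linear factor s on cell size and spacing (mean area falls by 1 - s^2,
distances by 1 - s); `degrade()` produces predicted cohorts with missed
cells, false positives, misclassification, boundary jitter and Beta
confidence scores.

## Worked example

```r
library(immunoseg)

# a single-stain FFPE-like cohort: 40 frames, ~31 cells each
cfg <- tissue_config(panel = "panel2", pixel_size_um = 0.1058,
                     fixation = "FFPE", n_frames = 40, cells_per_frame = 31,
                     class_mixture = c(CD4T = 0.35, CD4negT = 0.27,
                                       mDC = 0.07, pDC = 0.08, Bcell = 0.23),
                     seed = 1)
truth <- generate_truth(cfg)
truth
#> <cohort_dataset 'synthetic-truth'> role=truth frames=40 cells=1189

# degrade it like an imperfect detector and evaluate the round trip
dcfg <- degradation_config(panel_classes("panel2"),
                           detect_prob = c(CD4T = 0.90, CD4negT = 0.85,
                                           mDC = 0.38, pDC = 0.69,
                                           Bcell = 0.75),
                           fp_rate = 0.4, jitter = 0.1, seed = 2)
ev <- cross_evaluate(truth, degrade(truth, dcfg), theta = 0.25, tau = 0.3)
ev
#> <eval_summary> tau=0.3 theta=0.25
#> specificity := tp / (tp + fp), positive predictive value
#>  cell_class n_truth n_pred  tp fp fn sensitivity specificity iou_mean
#>        CD4T     406    371 363  8 43      0.8941      0.9784   0.9114
#>     CD4negT     357    324 316  8 41      0.8852      0.9753   0.9057
#>         mDC     102     47  36 11 66      0.3529      0.7660   0.9074
#>         pDC      77     56  48  8 29      0.6234      0.8571   0.9076
#>       Bcell     247    190 185  5 62      0.7490      0.9737   0.9086
#>      averaging sensitivity specificity iou_mean
#>  cell_weighted      0.7973      0.9595   0.9086
#>     class_mean      0.7009      0.9101   0.9081
```

The recovered sensitivities sit on the configured detection rates within
binomial noise (e.g. mDC 0.353 at a configured 0.38 over 102 cells), which
is exactly the loop the test suite checks at scale. Features and a
fixation contrast:

```r
ft <- cohort_features(truth)
head(ft$proximity[, c("t_cell_class", "nearest_dc_class", "distance_um")], 3)
#>   t_cell_class nearest_dc_class distance_um
#> 1      CD4negT              pDC    26.58129
#> 2         CD4T              mDC    20.30015
#> 3         CD4T              pDC    16.20910

ffpe <- generate_truth(apply_fixation_shrinkage(cfg, 0.667))
cmp <- compare_fixations(ft, cohort_features(ffpe), "fresh_frozen", "FFPE")
cmp[cmp$feature == "area_um2" & cmp$cell_class == "CD4T",
    c("mean_a", "mean_b", "percent_change", "ks_D", "p_value")]
#>     mean_a   mean_b percent_change      ks_D p_value
#> 1 49.98139 22.23534       55.51277 0.8300493       0
```

A shrinkage factor of 0.667 reduces mean CD4+ T-cell area by 55.5%
(1 - 0.667^2), and the KS test separates the two distributions at any
conventional level — the same analysis one runs between fresh-frozen and
FFPE feature tables from real predictions.

A thin command-line surface wraps the same functions
(`inst/cli/immunoseg.R`): `simulate`, `degrade`, `evaluate`, `features`,
`compare`, `report`, `split`, `convert` (polygon JSON <-> 16-bit label
TIFF + CSV sidecar), each writing CSV/JSON outputs plus a run manifest.

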