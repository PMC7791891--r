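---
title: "Quantifying immune-cell instance segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune-cell instance segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoseg)
```

## The problem

Multiplexed immunofluorescence imaging of inflamed tissue — the motivating
setting is lupus nephritis kidney biopsies — produces 1024 x 1024 pixel
confocal fields in which individual immune cells must be detected,
delineated pixel by pixel, and assigned to a phenotype: CD3+CD4+ T cells
(`CD4T`), CD3+CD4- T cells (`CD4negT`), myeloid and plasmacytoid dendritic
cells (`mDC`, `pDC`), and B cells (`Bcell`). Double-stain panels identify a
single DC type per image with two markers (frames tagged `panel1-mDC` or
`panel1-pDC`, three classes per frame); a single-stain panel identifies all
three antigen-presenting-cell populations at once (`panel2`, five classes
per frame). Tissue may be fresh-frozen or formalin-fixed and
paraffin-embedded (FFPE); formalin fixation dehydrates and contracts the
tissue, which changes every morphometric and spatial quantity downstream.

immunoseg implements the quantification layer of this workflow: cell-level
evaluation of predicted segmentations against manual ground truth,
physical-unit morphometry and intercellular distances, and the comparative
statistics used to contrast fixation methods and staining panels. Because
clinical images and trained segmentation networks are rarely shareable, the
package also ships a synthetic tissue simulator whose outputs exercise
every downstream stage with known ground truth. Predictions can come from
any source through the file interfaces; the simulator's degradation model
is a stand-in for a real predictor with controllable error structure.

## Evaluation protocol

A predicted cell is kept for analysis only if its confidence is *strictly
above* `tau = 0.3`. Retained predictions are matched one-to-one to manual
cells of the *same class* when their pixel-level intersection-over-union
(Jaccard index) is at least `theta = 0.25`. IOU is computed on rasters, not
polygon geometry, because the match criterion operates on segmentation
pixels: a pixel belongs to a cell when its center lies inside the outline
(even-odd rule; pixel (i, j) occupies the half-open unit square with corner
(j, i)).

The assignment is the maximum-cardinality matching over admissible pairs,
with ties broken by maximal total IOU, solved as a maximum-weight bipartite
matching with edge weight `IOU + (min(n_truth, n_pred) + 1)` — the constant
makes an extra pair always outweigh any redistribution of IOU, so the
solution is order-independent and reproducible, and an exhaustive
enumeration oracle can verify it exactly on small frames. A misclassified
overlap never forms a pair; it contributes one false negative and one false
positive.

Per class, counts are pooled over frames before ratios are formed
(micro-averaging): sensitivity is tp/(tp + fn). True negatives are
undefined for an instance-detection task, so the quantity reported under
the conventional name "specificity" is operationalized as the positive
predictive value tp/(tp + fp) over the class's predictions — the only
per-class cell-level quantity that responds to false positives. Every
summary and CSV records this definition. Overall rows are reported both
cell-weighted (sensitivity weighted by truth cells, specificity by
predictions, IOU by matched pairs) and as unweighted class means, because
published "average" columns are ambiguous between the two conventions.

## Morphometry and proximity

All physical features are in micrometres via the frame's pixel size
(0.1337-0.1413 um for the fresh-frozen imaging system, 0.1058 um for the
FFPE system in the emulated datasets).

* **Area** is the set-pixel count of the rasterized cell times the squared
  pixel size, so it agrees exactly with the masks used for matching.
* **Perimeter** is the length of the sub-pixel iso-contour of the mask
  (marching squares at level 0.5) after one corner-averaging smoothing pass
  of the closed contour. The raw mid-crack contour of a binary mask
  overestimates smooth boundaries by roughly 5% through staircase excess;
  one smoothing pass brings digital disks within about 2% of the true
  circumference while keeping the estimate above the isoperimetric bound
  `pi * equivalent_diameter`, so the reported records always satisfy that
  inequality up to a 1e-6 slack. The estimator's value on a 10 x 10 pixel
  square (37.899 px) is pinned by a golden test; boundary-pixel counting
  was rejected because it overestimates smooth cells by up to 4/pi.
* **Equivalent diameter** is `sqrt(4 * area / pi)`.
* **T-cell-to-DC distance** is the Euclidean distance from each T cell to
  the nearest mDC or pDC in its frame. B cells are never targets. The
  default reference point is the raster centroid, which is stable for
  amorphous dendritic cells; a boundary-vertex mode is provided because the
  literature rarely states which reference was used. The mode is recorded
  in every output row. T cells in frames without any DC are skipped and
  counted in a coverage attribute rather than silently dropped.
* Cells touching the frame border are flagged (possible truncation bias)
  but not excluded, since features are intended for every detected cell.

## The synthetic tissue model

`tissue_config()` + `generate_truth()` emulate one imaging condition.
Defaults were chosen once to reflect the emulated datasets and typical
lymphocyte biology:

| parameter | default | rationale |
|---|---|---|
| frame | 1024 px, 0.1058 or 0.1337 um/px | emulated acquisition systems |
| cells/frame | Poisson; 21.5-44.7 by dataset | published census densities |
| class mixture | census row proportions | per-dataset prevalence |
| areas (um^2, median, gsd) | T 48/1.35, B 45/1.35, mDC 95/1.5, pDC 72/1.45 | lymphocytes ~7-8 um equivalent diameter with little cytoplasm; DCs larger, more variable |
| shape irregularity | 0.08 T/B, 0.3 mDC, 0.2 pDC | DCs are amorphous with dendrites; lymphocytes near-round |
| aggregation | 3 clusters/frame, spread 12 um | immune infiltrates aggregate rather than tile uniformly |

Cells are placed cluster-then-scatter: cluster centers are drawn uniformly
in an inset box with a minimum-separation rejection step (default 3 x
spread; 60 attempts, then the most separated draw) so that aggregates are
spatially distinct, and each cell is displaced from its cluster center by
isotropic Gaussian noise truncated at the box margin. Cell shapes are
ellipses (axis ratio uniform on [0.6, 1]) whose boundary radius is
modulated by one random low-order harmonic with amplitude set by the
class's irregularity; radii carry two analytic corrections (inscribed
polygon, harmonic power) so the expected raster area equals the configured
log-normal mean without empirical calibration.

**Fixation shrinkage** is a single linear factor `s` in (0, 1] applied to
every cell's linear size and to within-cluster displacements, emulating
tissue contraction at constant cell count: mean area scales by s^2, mean
perimeter and nearest-neighbour distance by s, so a printed percent
reduction `p` in mean area corresponds to `s = sqrt(1 - p/100)`. Two
implementation details protect this scaling law. Displacements are
truncated *before* the factor is applied, so positions depend on `s` only
through the linear factor; and the minimum separation between clusters
keeps nearest-DC pairs within one aggregate, whose distances scale exactly.
(Without these, boundary clamping and cross-cluster neighbours bias the
recovered distance ratio by a few tenths of a percentage point, enough to
fail a 3-standard-error check at several thousand cells.)

**Determinism.** Each frame consumes an independent random stream derived
from the master seed, so frame k is bit-identical whether 10 or 1000
frames are requested, and `shrinkage_s = 1` under the same seed reproduces
the unshrunk cohort draw for draw. This also supports paired
(common-random-numbers) contrasts: the same seed at two shrinkage factors
yields the identical cohort scaled by `s`, isolating the fixation effect
from cohort sampling noise; the acceptance script uses this design for its
shrinkage quantities, while the test suite also verifies recovery with
independent seeds within 3 SE.

**Degradation model** (`degradation_config()` + `degrade()`): each truth
cell is detected with a per-class probability; detected cells receive a
confusion-sampled class, a boundary jitter (radial harmonic + translation,
amplitude as a fraction of equivalent radius — the jitter-to-IOU
relationship is left as an empirical knob), and a confidence drawn from a
Beta distribution for correct detections (default Beta(20, 2)) or from an
error distribution (default Beta(2, 4)) for misclassifications.
Per class and frame, Poisson false positives are placed uniformly with
shapes resampled from the cohort's own cells of that class — the simplest
null — and error-distribution confidences. Because both distributions live
on [0, 1] with mass below 0.3, the confidence filter is meaningful: it
removes roughly half of the false positives at the defaults while leaving
correct detections essentially untouched, which is how the evaluator can
recover the configured detection probabilities.

What the simulator deliberately does **not** model: fluorescence
intensities, spectral bleed-through, autofluorescence, out-of-plane
dendrites, nucleus-containment constraints, or inter-observer variability
in manual outlines. Passing tests therefore demonstrate that the
*quantification* pipeline is correct and unbiased under a controlled error
structure — not that any particular network achieves the emulated rates on
real tissue.

## Comparative statistics

`ks_two_sample()` is the two-sample Kolmogorov-Smirnov test on the maximum
ECDF difference. The default p-value is asymptotic (effective sample size
n1 n2 / (n1 + n2)), appropriate for cohort-scale samples; an exact option
exists for small-sample work. No multiple-testing correction is applied —
comparisons mirror per-panel reporting conventions — but the number of
tests performed is recorded with the results. `percent_change_of_means()`
is signed so that positive values are reductions relative to the reference
(fresh-frozen) group. Population tables print cells/image at 1 decimal and
class percentages at 2 decimals using round-half-up, the convention that
reproduces most printed census cells; a handful of published cells appear
truncated instead and are not reproducible by any consistent rounding of
their own counts.

`split_dataset()` shuffles frames by seed and apportions partitions by
largest remainder, so each partition differs from its exact share by less
than one frame (160 frames at 90/5/5 gives 144/8/8). Splitting operates at
the image level: frames from one biopsy may land in different partitions,
which holds patient composition constant across partitions at the cost of
non-independence between them — the appropriate design when the quantity
under study is a protocol difference rather than patient generalization.

## Numerical choices and degenerate inputs

* Rasterization uses an even-odd scanline fill; pixel centers at
  half-integers never lie on polygon edges with integer-corner outlines,
  so label-map round-trips are exact. Degenerate polygons (< 3 vertices,
  zero area, empty raster) are rejected with the instance id.
* `iou()` returns 0 with a warning when both masks are empty; dimension
  mismatches error with both shapes.
* Label maps cannot encode overlap (touching cells may overlap in manual
  outlines, which is why polygons are the canonical format). Export offers
  a strict mode (error listing colliding ids) and a precedence mode
  (higher confidence wins contested pixels, ties to the earlier instance).
* `polygonize()` traces label boundaries along pixel edges; diagonally
  pinched regions become one weakly simple outline (left turn at pinch
  vertices), and genuinely disconnected labels are rejected rather than
  silently merged.
* Matching tie-breaks (equal-IOU alternatives of equal cardinality) may
  admit several optimal assignments; the solver returns one, and every
  reported metric (pair count, per-class counts, IOU totals) is invariant
  across optima up to the 1e-12 weight resolution.
* Classes with no truth and no predicted cells report `NA` ratios flagged
  by a `defined` column, never silent zeros.

## Problem sizes used by the shipped checks

The test suite and acceptance script scale the simulations to keep every
stochastic estimate at or above 2000 cells per pooled class: 200 frames of
~31 cells for detection-rate recovery, 120 x 60 (tests) or paired 100 x 60
(acceptance script) for shrinkage recovery, 1000 small random frames for
matcher-oracle equivalence, and 2000 same-distribution replicates for KS
calibration. These sizes were chosen as the smallest giving 3-SE bands of
about one percentage point on the recovered quantities.

## Known limitations

Single 2-D planes only (no volumetric features); no raw-pixel data model
(the package starts at instances); the one-to-one matching decision means a
duplicate detection counts as a false positive rather than being merged;
specificity-as-PPV is an interpretation forced by the absence of true
negatives in instance detection; and simulated DC shapes, while irregular,
do not reproduce true dendrite morphology, so absolute DC perimeter
distributions should not be over-interpreted.
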