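---
title: "Segment-wise multiloss refinement: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-wise multiloss refinement: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avrefine)
```

## The model

Retinal arterioles and venules are anatomically coherent objects: between
two branch or crossing points a vessel has one identity. A per-pixel
classifier ignores this and makes isolated artery/vein confusions,
concentrated on thin vessels (local width under four pixels), which
dominate retinal vasculature. The segment-wise multiloss judgment imposes
the anatomical constraint after the fact.

Write the vessel mask's medial skeleton as $J_s$, cut at junctions into
segments $S_j$, $j = 1, \dots, N$. Each mask pixel is attached to the
segment of its nearest skeleton pixel, giving vessel-pixel sets $V_j$ and
mean thicknesses

$$TV_j = \frac{|V_j|}{|S_j|}.$$

Inside each $V_j$ the pixel-wise predictions are tallied into an artery
fraction $f_a$ and a vein fraction $f_v$ (fractions of all vessel pixels
of the segment; pixels the classifier called background carry no vote,
because the decision is artery-versus-vein). With segment-level losses
$P_{artery} = 1 - f_a$ and $P_{vein} = 1 - f_v$, the judgment is

$$\text{judgment} = \max(1 - P_{artery},\; 1 - P_{vein}),$$

i.e. the majority predicted class; all pixels of the segment take it. A
tie falls back to the pixel-wise softmax labels (configurable).

For diagnostics, the reference segment is matched to its predicted
counterpart: $R_j$ is the smallest dilation radius of $V_j$ that achieves
the maximal overlap with the predicted vessel mask (searched up to
`r_max`, default 10 px), $Vs'_j$ the predicted pixels inside that range,
and the mismatch ratio

$$\mathrm{MisR} = \frac{|TV'_j - TV_j|}{TV_j}$$

weights per-pixel losses as $w_p = 1 + \mathrm{MisR}$ inside $Vs'_j$ and
$1$ elsewhere; the weighted loss of a probability raster against a
reference label is $(1 - p(\text{true class}))\, w_p$ per pixel. Since no
network is trained here, the weighted loss is an evaluation and
diagnostic quantity, not a training signal.

### Why a majority vote succeeds

If per-pixel errors are independent flips at rate $\varepsilon < 0.5$, a
segment with $n$ vessel pixels is judged correctly with probability at
least $1 - \exp(-2n(0.5 - \varepsilon)^2)$ (Hoeffding). At $n = 100$ and
$\varepsilon = 0.2$ the exact binomial failure probability
$P[\mathrm{Bin}(100, 0.2) \ge 50]$ is below $10^{-9}$: segments of
realistic size are essentially always recovered, which is what the test
suite verifies both by the exact tail and by seeded Monte-Carlo.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.5 | vessel probability cut for `binarize()` (inclusive `>=`; artery wins exact artery/vein ties, configurable) |
| `max_length` | none | maximum segment length in px; longer segments are split into consecutive runs |
| `min_length` | 1 px | segments with fewer skeleton pixels are dropped; their vessel pixels fall to the nearest surviving segment |
| `tie_policy` | keep | tied segments keep pixel-wise labels (or force artery/vein) |
| `r_max` | 10 px | search bound for the matching range $R_j$ |
| BF tolerance | 0.75% of the image diagonal | boundary-match distance for the boundary F-score (the de-facto convention) |
| decode tolerance | 60 | max Euclidean RGB distance from a palette color (8-bit scale), absorbing lossy-compression artifacts |
| `low/high_saturation` | 2% / 3% | percentile saturation of the contrast stretch |
| `closing_radius` | 2 px | optional binary closing of the vessel tree in label enhancement |
| `min_component_area` | 30 px | specks smaller than this are removed, enclosed holes smaller than this are filled (chosen for ~565-px-wide images; scale with the diagonal) |

## The synthetic generator

`generate_case()` emulates the geometry the judgment relies on, not the
photometry of fundus images. Trees of the two classes radiate outward
from a disc origin (as vessels do from the optic disc), classes
alternating around the rim so neighbouring vessels tend to be of contrary
type. Each branch is a discrete biased random walk with angular momentum,
a gentle outward radial pull, and a stamped disc of its width; children
branch off at 20–60° with width multiplied by `width_decay` (floor 1 px),
so a parent is never thinner than its branches. A branch terminates
rather than cross a same-class vessel; opposite-class crossings are
allowed (the later vessel passes on top), but a walk that stays within
2 px of an opposite-class vessel for longer than a crossing would take is
terminated — parallel vessels of contrary type exist in retinas, merged
tangential runs do not, and they would create mixed-class skeleton
segments.

Defaults (`root_width = 4`, `width_decay = 0.7`, `branch_prob = 0.03`,
`max_depth = 3`, 2 trees per class on 256×256) put roughly a third of the
vessel pixels in the sub-4-px thin regime, the regime that motivates
segment-level judgment; `thin_vessel_fraction()` reports the share.

The corrupted prediction flips each vessel pixel's class independently
with `flip_rate` and can dilate/erode the predicted mask by
`thickness_jitter`. The probability raster assigns the predicted class
$0.5 + u$ with $u \sim U(0, 0.4]$ and a small background mass, so
`binarize()` at 0.5 reproduces the hard prediction exactly — the hard and
soft paths stay mutually consistent. Identical seeds give bit-identical
cases (Mersenne–Twister, integer seeds).

What the generator does **not** emulate: image photometry (no optic disc
rendering, no central light reflex, no pathology), spatially correlated
classifier errors, and vessel-segmentation errors beyond uniform boundary
jitter. Passing tests therefore demonstrate the correctness and the
noise-suppression behaviour of the judgment under independent noise on
plausible geometry — not performance on real fundus images, which
additionally depends on the upstream pixel classifier.

## Numerical choices

* **Thinning.** Zhang–Suen thinning followed by a sequential deletion of
  8-simple non-endpoint pixels (Yokoi connectivity number $C_8 = 1$,
  $\ge 2$ neighbours). Zhang–Suen alone leaves two-pixel staircase
  corners whose neighbour counts mimic junctions; simple-pixel deletion
  is connectivity- and hole-preserving, so the skeleton keeps the mask's
  topology at unit width.
* **Junctions.** Skeleton pixels with $\ge 3$ skeleton neighbours
  (8-connectivity), bifurcations and crossings alike. At a crossing of
  two 1-px lines this marks the centre *and* its four arm neighbours
  (they gain diagonal contacts across the crossing); removing the whole
  cluster is exactly what separates the four arms — deleting only the
  centre would leave them diagonally connected.
* **Nearest-segment partition.** Exact Euclidean distances on integer
  squared distances; ties go to the lower segment id, then to the earlier
  pixel in path order, making the partition deterministic and equal to
  the brute-force all-pairs assignment (tested on rasters up to 64×64).
* **Maximum local diameter.** $T_p = 2 \max_{p \in S_j} d(p)$ with $d$
  the Euclidean distance transform of the mask, a half-pixel
  over/under-estimate depending on width parity. The per-pixel summand of
  the segment length statistic is constant along a segment, so the
  statistic collapses to $T_p - TV_j$; it is reported as a
  width-inhomogeneity diagnostic and drives no control flow. The usable
  maximum-length behaviour is the explicit `max_length` split.
* **Mismatch ratio.** Absolute thickness difference: a signed difference
  would hand weights below 1 to too-thin predictions, rewarding the
  mismatch it is meant to penalize.
* **Weighted loss.** Operationalized as the L1 deviation of the predicted
  probability of the reference class from one, times $w_p$ — the natural
  reading of a prediction-minus-label difference for categorical labels.
* **Percentile stretch.** Inverse-ECDF (type-1) quantiles. This makes the
  stretch idempotent on its own output: after one pass at least 2% of the
  mass sits exactly at the minimum and more than 3% at the maximum, so a
  second pass maps the range to itself. A constant image is returned
  unchanged (degenerate quantiles).
* **Ties.** Binarization ties artery-over-vein (deterministic,
  configurable); judgment ties follow `tie_policy`; enhancement segments
  with no manual vote take the class of the nearest labelled vessel
  pixel.
* **Degenerate inputs.** Empty masks skeletonize to empty skeletons; an
  all-background comparison raises an explicit error rather than 0/0;
  classes absent from both rasters are excluded from metric means.

## Design choices that were genuinely open

* **Minimum segment length as a dissolve, not a skip.** Dropping sub-25-px
  skeleton runs *before* the partition sends their vessel pixels to the
  nearest surviving segment, so every vessel pixel is still judged —
  short spurs inherit their parent vessel's judgment instead of keeping
  unrefined noise.
* **Background votes.** Pixels predicted background inside the mask
  dilute both fractions but vote for neither class: the judgment has
  exactly two terms.
* **Overlapping matched segments.** A pixel covered by several $Vs'_j$
  takes the largest weight (the most pessimistic mismatch).
* **Per-image metric aggregation.** Dataset metrics average per-image
  values unweighted; whether background counts as a scored class is
  exposed (`classes = "all"` or `"vessel"`), defaulting to all three.
* **The worked-example table.** Two printed rows are internally
  inconsistent: one prints counts (400 red / 100 blue) contradicting its
  printed judgment, another's counts sum past its printed total. The
  fixture flags both; fraction checks use the count sum as denominator
  where needed and the judgment check skips the count-contradicted row.

## Problem sizes

The test suite and the acceptance script use 20 synthetic cases at
256×256 with 20% flip noise and a 25-px minimum segment length for the
refinement suite, 1,000 replicates of 100 votes for majority-vote
recovery, rasters up to 64×64 for brute-force oracle equivalence, and the
12-row worked-example table. On one CPU the whole suite runs in well
under a minute.

## Known limitations

* Opposite-class crossings inherently mix a few dozen pixels per crossing
  into segments of the other class; refined vessel-pixel accuracy
  saturates slightly below 1 even with perfect judgments.
* The skeleton retreats ~half a vessel width from blunt vessel ends, so
  end pixels can sit slightly beyond the local radius of the nearest
  skeleton pixel.
* Junction clusters claim their vessel pixels for neighbouring segments;
  at dense junction clusters segment thickness is a mild overestimate.
* The weighted loss is a diagnostic: nothing here trains a classifier.
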