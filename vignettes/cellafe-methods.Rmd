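---
title: "Methods: automatic feature extraction and neuro-fuzzy classification of single-cell cervical images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic feature extraction and neuro-fuzzy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellafe)
```

## The problem

Cervical-cytology screening classifies single squamous cells as normal,
LSIL (low-grade squamous intraepithelial lesion) or HSIL (high-grade).
The morphological signal is simple and strong: abnormal cells have an
enlarged, darker nucleus and a shrunken cytoplasm. `cellafe` implements a
classical two-stage recognition pipeline over 8-bit grey-level
single-cell images (nominally 160 × 120):

1. **Automatic feature extraction (AFE)** — segment the image into
   nucleus, cytoplasm and background and measure six features: nucleus
   size, perimeter and mean grey level, and the same three for the
   cytoplasm.
2. **MANFIS classification** — three parallel first-order Sugeno ANFIS
   models map the six features to per-class scores; the argmax is the
   predicted class.

## Stage 1: automatic feature extraction

### Grey-level clustering and thresholds

A single-cell image has three grey-level populations, darkest to
brightest: nucleus, cytoplasm, background. `moving_k_means()` clusters
the 256-bin grey histogram into three clusters. Clustering the histogram
rather than the pixel list is an exact reformulation for 1-D data and is
orders of magnitude faster.

Moving k-means differs from plain k-means by a relocation step that
prevents empty or poorly fitted clusters: after each assignment/update
pass, the within-cluster fitness (weighted sum of squared distances to
the centre) is compared across clusters, and while the smallest fitness
is below $\alpha_a$ times the largest, the smallest-fitness cluster
abandons its members and takes over the members of the largest-fitness
cluster that lie below that cluster's centre; $\alpha_a$ shrinks by a
third at each move ($\alpha \leftarrow \alpha - \alpha/n_c$, $n_c = 3$).
A second threshold $\alpha_b$ drives a verification pass after
convergence. Defaults $\alpha_a = \alpha_b = 0.3$, tolerance $10^{-3}$
grey levels, at most 100 passes. An earlier variant that let the
small cluster *keep* its old members while receiving donated ones fails
on realistic histograms (the donated dark pixels average into a
background cluster); the abandon-and-relocate form recovers the three
grey modes to within half a grey level at noise SD 5.

Initial centres come from a deterministic histogram analysis: the median
grey level of each of the three equal-mass segments of the cumulative
histogram. When one region dominates the frame, the three mass tertiles
can collapse onto one grey level; the method then falls back to
mass-weighted medians of the equal-*width* tertiles of the occupied grey
range (and finally to segment midpoints). Either way the result is three
strictly increasing centres or an explicit degenerate-histogram error
(fewer than three distinct grey levels).

The two segmentation thresholds are midpoints of adjacent final centres,
truncated to integers:

$$\beta_{NC} = \lfloor (C_N + C_C)/2 \rfloor, \qquad
  \beta_{CB} = \lfloor (C_C + C_B)/2 \rfloor.$$

Truncation (not rounding) is used so that centres such as 153/190
produce 171, matching the convention of the reference measurements this
package reproduces.

### Seed location

Segmentation grows from a seed inside the nucleus. `nucleus_centroid()`
finds it by *subclustering*: a region grown from the corner pixel (0, 0)
— background in any well-framed single-cell image — absorbs 8-connected
pixels brighter than $\beta_{CB}$, then remaining connected pixels
brighter than $\beta_{NC}$. What is left dark and unconnected is the
candidate nucleus. Its centre is the rounded raw-moment centroid
$(m_{10}/m_{00},\, m_{01}/m_{00})$; only zeroth/first moments are needed
for a location, so no higher-order invariant moments are computed. If
the rounded point is not itself on the mask (possible for crescents), it
snaps to the nearest mask pixel, ties broken in row-major order. A dark
corner pixel raises a seed-in-foreground error rather than silently
growing the wrong region.

### Region growing with simultaneous feature extraction

`segment_and_extract()` runs two breadth-first 8-connected growths from
the same seed: a nucleus pass with $\beta_{NC}$ and a cytoplasm pass
with $\beta_{CB}$. A neighbour pixel is accepted when either

* (a) the gradient between its original grey level and its
  histogram-equalized grey level is **below 95%** and the original grey
  level is **at or below** the pass threshold, or
* (b) the gradient is at or above 95% and the original grey level is at
  least $\bar{x} - \sigma$, the running mean minus the running standard
  deviation of the grey levels accepted so far.

Choices worth recording:

* The threshold test accepts *dark* pixels ($\le \beta$). The printed
  step list of the source procedure says "equal or greater", but its own
  worked discussion and the grey-level ordering (nucleus darkest) make
  clear that growth must absorb the dark side; the greater-than reading
  would grow the background from a dark seed.
* "Gradient" is not defined in the source; we use
  $|g_{eq} - g_{orig}|/255 \times 100$, a bounded percentage, with the
  cutoff exposed as the `cutoff` argument (default 95).
* The original (unfiltered) grey level feeds both the threshold test and
  the running statistics; the median filter (3 × 3, edge-replicated) and
  histogram equalization (`round(255·cdf)`) only produce the equalized
  value used by the gradient. On noise-free images branch (a) is then
  purely pixel-local, which is what makes exact ground-truth recovery
  possible.
* Growth order is FIFO breadth-first with neighbours enqueued E, SE, S,
  SW, W, NW, N, NE, and every pixel is examined at most once. Because
  branch (b) depends on the running statistics, the grown set can in
  principle depend on the visit order; fixing the order makes runs
  deterministic. $\sigma$ is defined as 0 for a single accepted pixel
  (the $n-1$ denominator is otherwise undefined).
* Perimeters are *border pixel counts* (members with a non-member or
  out-of-image 8-neighbour), not geometric contour lengths.

The cytoplasm pass starts from the same seed and regrows the nucleus, so
its raw size includes the nucleus; the actual cytoplasm size is
$c = \text{cytoplasm size} - n$ and its mean grey level
$(\sum GL_C - \sum GL_N)/c$. A cytoplasm pass that grows nothing beyond
the nucleus raises a degenerate-cytoplasm error ($\bar{GL}_C$ would be
0/0). The mask labels nucleus 0, additional cytoplasm growth 127,
everything else 255 — written bit-exactly by `write_grey_image()`.

## Stage 2: MANFIS

`manfis()` fits one first-order Sugeno ANFIS per class over the six
features, one-vs-rest with targets 1/0, and classifies by argmax (ties
go to the earlier class in normal → LSIL → HSIL order). The reference
description states no hyperparameters, so the package adopts canonical
ANFIS defaults and exposes them:

* **Membership functions**: 2 generalized bells per input,
  $\mu(x) = 1/(1 + ((x-c)/a)^{2b})$, centres at 0 and 1 on the
  normalized scale, $a = 0.5$, $b = 2$. Grid partition gives
  $2^6 = 64$ rules, each with a 7-coefficient linear consequent.
* **Normalization**: per-feature min–max to [0, 1], fitted on training
  data only; prediction inputs are clipped into the bounds. The raw
  features span two orders of magnitude ($\sim 10^2$ px nuclei vs
  $\sim 10^4$ px cytoplasms), so commensurate scales are required for
  the bells to partition meaningfully.
* **Hybrid learning** (default 50 epochs): per epoch, an exact
  least-squares solve of all 448 consequent coefficients with premises
  fixed, then one backpropagation step (analytic gradients, validated
  against central finite differences) on the bell parameters with
  learning rate 0.01, halved — and the step reverted — whenever it
  increases the training SSE. With 448 coefficients against 400
  training rows the consequent solve is under-determined, so it is
  ridge-regularized ($\lambda = 10^{-6}$), giving a minimum-norm-like
  interpolating solution.

Training is deterministic given the data; the `seed` argument is
recorded with the model so that stochastic wrappers (fold sampling)
reproduce exactly.

## Evaluation protocol

`run_crossval()` draws five **independent random 80/20 splits** rather
than a disjoint 5-way partition. This mirrors the reference protocol,
whose per-fold class counts vary from fold to fold in a way a disjoint
partition of a fixed population cannot produce. Accuracy is
$100 \times \text{correct}/\text{total}$; per-class accuracy pools
correct and original counts over all folds before dividing; overall
accuracy is the unweighted mean of per-fold accuracies. Reports round
half-up to one decimal — half-up, not banker's, because fold accuracies
like 385/400 = 96.25 must print as 96.3 to match the reference report's
arithmetic.

## Synthetic data

No clinical images are distributed with the reference measurements, so
the package generates its own ground-truthed data.

`generate_cell_image()` rasterizes a cell as two (optionally offset)
disks — dark nucleus inside mid-grey cytoplasm on a bright background —
plus independent per-pixel Gaussian noise, rounded and clipped to
[0, 255]. Default grey centres 153/190/227 and default radii 10/54
reproduce a typical normal cell's grey-level structure and
nucleus/cytoplasm areas (≈314/8846 px against typical measured values
337/8859 px), with the cell filling about half the 160 × 120 frame as in
real single-cell crops. The default noise SD is 5 grey levels, the
largest perturbation at which the pipeline is expected to stay within a
few percent of ground truth. `cell_spec_preset()` provides per-class
geometry and grey levels (normal: small nucleus/large cytoplasm; HSIL:
large nucleus/small cytoplasm).

One genuine limitation surfaced during design: with a frame that is
~85% background (e.g. cytoplasm radius 30 in a 160 × 120 image), the
mass-weighted MKM fitness prefers splitting the dominant background over
separating the small dark nucleus — a real property of the algorithm,
not a bug. The generator's default geometry therefore matches the
realistic cell-filled framing; heavily background-dominated crops are
outside the calibrated regime.

`generate_feature_dataset()` draws six-feature vectors from independent
Gaussians around per-class mean vectors (defaults: the typical measured
normal/LSIL/HSIL values) with spreads of 10% of each mean — moderate
acquisition variability chosen once as a realistic screening population;
the default class sizes 376/79/45 reproduce the usual normal-heavy
screening mix. What the synthetic data does *not* emulate: staining and
texture variation, feature correlations within a cell, overlapping or
multiple cells, and class-boundary ambiguity of real LSIL/HSIL cells.
Passing tests on these fixtures demonstrates algorithmic correctness and
internal consistency, not clinical performance.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run, by the package's own choice,
at these scales: full 160 × 120 images for the end-to-end pipeline
checks; random 32 × 24 / 8 × 8 images against brute-force oracles; the
500-row (376/79/45) synthetic feature population for the five-fold
MANFIS evaluation with the default 50 training epochs; toy 2–3 input
ANFIS models for gradient and normal-equations oracles.

## Known limitations

* Running mean/σ make the grown region order-dependent in branch (b);
  this is inherent to the published growth rule and is fixed only by the
  deterministic visit order.
* The subclustering seed must be background; images whose corner pixel
  is dark are rejected rather than re-seeded.
* MKM on background-dominated frames (above).
* The classifier's near-perfect synthetic accuracy reflects the
  separability of the synthetic classes; real cytology features overlap
  far more.
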