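---
title: "Assessing wheat lodging from UAV point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing wheat lodging from UAV point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodgepoint)
```

## The problem

Lodging — the permanent displacement of crop stems from the vertical by
wind, rain or hail — reduces both grain quality and harvestable yield.
Assessing *how much* of a field has lodged, and *how severely*, matters for
yield estimation, harvest planning and insurance claims. Photogrammetric
point clouds reconstructed from overlapping UAV images capture the canopy's
horizontal and vertical structure at once, but their clutter (millions of
unordered 3D points, no topology) makes them awkward inputs for standard
image classifiers.

`lodgepoint` implements a dimensionality-reduction pipeline that turns a
field point cloud into per-plot 2D canopy-height images, scores each plot
with a lodging index, and trains convolutional networks to recognise four
lodging degrees from the images. Every stage is testable against a bundled
synthetic wheat-field generator with known ground truth.

## Lodging geometry and the double-threshold labels

For a plot whose plants have sloping stem length $h_1$ and canopy height
$h_2$, the lodging angle from the vertical is

$$\theta = 90^\circ - \arcsin(h_2 / h_1),$$

so an upright plant ($h_2 = h_1$) has $\theta = 0$ and a flat one
($h_2 = 0$) has $\theta = 90^\circ$. The angle score $LA = 2\theta/\pi$
rescales this to $[0, 1]$, and the lodging index combines it with the
lodged-area fraction $LR$ of the plot:

$$LI = LA \times LR \in [0, 1].$$

Field protocols typically measure 3–5 $(h_1, h_2)$ sample pairs per plot;
`measure_plots()` averages the per-sample angles before computing $LA$.

Classes come from a double-threshold scheme on the survey's $LI$
distribution: with mean $\mu$ and *population* standard deviation
$\alpha$, the intervals $[0, \mu-\alpha)$, $[\mu-\alpha, \mu)$,
$[\mu, \mu+\alpha)$, $[\mu+\alpha, 1]$ define non-lodging, slight,
moderate and severe lodging. The reference survey values $\mu = 0.40$,
$\alpha = 0.274$ give cut points 0.126 / 0.40 / 0.674 and can be injected
directly:

```{r}
thr <- lodging_thresholds(mu = 0.40, alpha = 0.274)
thr
classify_li(c(0.05, 0.3, 0.5, 0.8), thr)
```

Two conventions required a decision. Published interval notation overlaps
at the cut points, so we use right-open intervals (a boundary value belongs
to the more severe class), making classification deterministic and
monotone. And $\alpha$ uses the divide-by-$n$ standard deviation for
consistency with the population covariance convention used throughout.

## From cloud to image

**Ground separation.** Each point's Excess Green index is computed on
chromatic coordinates, $ExG = 2g - r - b$ with $g = G/(R+G+B)$ etc., so
soil scores near zero and green canopy near its theoretical maximum of 2.
Points below the threshold (default 0.0729) are ground. The chromatic form
was chosen because the default threshold is only meaningful on that scale —
the raw form $2G - R - B$ ranges over $\pm 510$. The split direction
(ground = *below* threshold) follows from green vegetation scoring high.

**Height normalization.** A digital elevation model is interpolated from
the ground points (inverse-distance weighting on a 0.1 m grid), and each
point's height becomes $z - \mathrm{DEM}(x, y)$ with bilinear DEM sampling.
Negative heights are kept: clamping would hide interpolation bias, and
rendering clips anyway.

**Principal-axes alignment.** The Hotelling transform
$P' = V\,(P - m)$ — with $m$ the centroid, $C$ the population covariance
and $V$'s rows the eigenvectors of $C$ in descending-eigenvalue order —
rotates each plot into the frame where its long side, short side and
height lie on axes 1, 2, 3 and the covariance is diagonal. Eigenvector
signs are pinned (height axis up, first axis toward world $+x$, second
axis their cross product) so the output is deterministic and a proper
rotation (det $V = +1$, no mirrored fields). Because the transform centres
*every* axis, `align_plot()` re-adds the centroid's height component along
axis 3 by default, keeping values on the above-ground datum that the
rasters display.

**Rasterization.** The aligned plot is gridded with
$rows = \mathrm{round}(\Delta x / d)$, $cols = \mathrm{round}(\Delta y / d)$
(half-away-from-zero rounding, so a 7.8 m × 3.8 m plot at $d = 0.01$ m is
exactly 780 × 380) and cell-centre heights are interpolated by IDW:

$$Z = \sum_i K_i Z_i, \qquad
K_i = \frac{d_i^{-2}}{\sum_j d_j^{-2}},$$

with $d_i$ the planimetric distance to sample $i$. The weights are convex,
so every cell value lies within its neighbours' extremes. Two numerical
choices: the literal formula sums over *all* samples, which is
$O(\text{cells} \times \text{points})$; the default uses the 12 nearest
neighbours, with `k_neighbors = 0` switching to the exact form (the two
are verified to agree in the test suite). And the weight formula is
singular at $d_i = 0$, so cell centres within `exact_hit_eps` of a sample
take the mean of the coincident samples. Interpolation quality is measured
by seeded random holdout: residuals $w_i$ = predicted − actual give
MAE $= \overline{|w_i|}$, SD $= \sqrt{\overline{w_i^2}}$ and the median of
$|w_i|$, reported in millimetres (the median is taken on absolute
residuals, matching the all-positive convention of published error
tables). A benchmark table of per-method errors ships with the package and
`interp_error_reduction()` turns it into percentage reductions of IDW
against the comparison interpolators; alternative interpolators can be
plugged in through `register_interpolator()`.

Rendering clips heights to $[z_{\min}, z_{\max}]$ (default $[0, 1.2]$ m)
and maps them through a perceptually uniform palette (viridis; the choice
is free, a palette merely has to be fixed and monotone).

## The classifiers

`build_model()` constructs AlexNet, VGG16 or MobileNetV2 with the
classifier head resized to the four lodging degrees, on a small in-package
CNN engine (im2col convolutions, batch normalization, ReLU/ReLU6 and
pooling layers, Adam, cross-entropy; backpropagation is verified against
numerical gradients in the test suite). Layer shapes follow the canonical
published architectures, so trainable parameter counts at 1000-class
output reproduce the reference values exactly — 138,357,544 for VGG16 and
3,504,872 for MobileNetV2 (batch-norm scale and shift counted as
trainable; running moments are buffers). The canonical AlexNet counts
61,100,840 parameters; published variants differ and no particular one is
targeted.

Training follows the reference protocol: Adam at learning rate 0.001,
batch size 4, cross-entropy loss, at most 400 epochs with early stopping
once the monitored validation metric — we monitor validation accuracy,
with ties keeping the earlier epoch — has not improved for 30 consecutive
epochs; the best-validation weights are restored. Runs are fully seeded:
the same configuration reproduces the same history bit for bit.

One stabilisation is applied at construction time: the projection
batch-norm scale of every residual block is zero-initialised, so each
block starts as the identity. Training MobileNetV2 from random
initialisation at batch size 4 otherwise suffers exploding backward noise
through its ~50 batch-norm layers (tiny per-batch variances at late,
spatially collapsed stages); zero-gamma initialisation is a standard
remedy and does not change the parameter count.

**Dataset construction.** Rasters are rendered, resized to a square
network input with bilinear resampling and channel-normalized with the
conventional RGB statistics. `augment_dataset()` keeps the originals and
appends seeded random rotations (90°/270°) and horizontal/vertical flips
until the requested total — e.g. 360 originals augmented to 1,000. The
16:4:5 split (1,000 → 640/160/200) is a seeded, stratified shuffle with
largest-remainder rounding. Augmentation before splitting mirrors the
reference dataset's counts, but it lets augmented copies of one source
plot land in different splits; for honest generalization estimates on real
data, split by source plot first (the manifest records `source_plot` for
exactly this reason).

**Evaluation.** From the confusion matrix, per-class one-vs-rest TP/FP/
TN/FN give precision, recall and F1; we report macro averages (the
symmetric default when no averaging rule is stated) alongside overall
accuracy. Classes absent from the test set are flagged and excluded from
macro averages.

## The synthetic field generator

`generate_plot()` emulates a surveyed wheat plot: a 7.8 m × 3.8 m
footprint, uniform point positions at ~500 points/m², gently undulating
terrain (plane plus sinusoid, amplitude 0.05 m), a green canopy at
$h_1 = 1$ m with Gaussian height noise ($\sigma$ = 0.02 m), about a fifth
of points as brown soil returns, and a contiguous lodged patch of area
fraction $LR$ where the canopy sits at $h_1 \cos\theta$ — the geometric
inverse of the lodging-angle formula, so the lodging module recovers the
injected $\theta$ exactly in expectation. Patches are axis-aligned
rectangles by default (a circular option exists); colours are jittered
around canopy-green and soil-brown means chosen so the default ExG
threshold separates them cleanly.

What the generator does *not* emulate: photogrammetric reconstruction
noise (correlated, height-dependent), plant-scale canopy structure,
mixed-pixel colours at patch borders, and within-plot height gradients.
Passing tests therefore demonstrate that the pipeline's geometry,
interpolation and learning machinery are correct — not that field
classification accuracy on real surveys is reproduced.

`generate_band_field()` produces the classifier study condition: plots
whose canopy heights fall in four cleanly separated bands (non-lodging
above 0.9 m, slight 0.7–0.9 m, moderate 0.5–0.7 m, severe below 0.5 m,
drawn with small margins inside each band), the whole plot lodged for the
three lodged classes.

## Desk-scale experiment sizes

The test suite and the worked examples run the full pipeline at reduced
problem sizes, chosen once as representative rather than exhaustive:
synthetic plots at 120 points/m², rasters at 0.1 m spacing (78 × 38),
network inputs of 16–32 px, MobileNetV2 at width multiplier 0.25, and a
dataset of 84 source plots augmented to 325 images (208/52/65 after the
16:4:5 split). The four-band experiment trains with batch size 16: the
protocol's batch size 4 is kept as the package default, but at desk scale
it leaves from-scratch training noise-limited by tiny-batch batch-norm
statistics on near-uniform rasters (see limitations), and the batch size
is not the quantity the band experiment studies. At this scale the
experiment trains in minutes on one CPU core. The paper-scale settings (0.01 m
rasters, 224 px inputs, width 1.0, 400-epoch budget) are plain parameter
changes, not different code paths.

## Known limitations

* The IDW neighbour search is a chunked vectorised brute-force scan — fine
  for per-plot rasters up to a few thousand cells × 10^5 points, slow far
  beyond that.
* The CNN engine is plain R: correct and deterministic, but orders of
  magnitude slower than a GPU framework; paper-scale training runs are out
  of its intended range.
* Batch-norm statistics at batch size 4 remain noisy on images that are
  nearly uniform spatially (the band rasters are close to this regime);
  zero-gamma initialisation mitigates but does not remove this, and
  desk-scale runs may use a larger batch when the protocol's batch size is
  not the quantity under study.
* Lodged-area fraction is an input (measured in the field or injected by
  the generator); estimating it from imagery is out of scope.
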