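---
title: "Localizing dense small objects from sparse point annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing dense small objects from sparse point annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Counting and localizing dense small objects — cell nuclei in histology
sections, cells in microfluidic droplets, insects, heads in a crowd —
is usually cast as density-map regression, which needs a click on
*every* object in the training images.  When an annotator marks only a
handful of objects per image, the unmarked remainder is not background:
it is a mixture of background and unannotated objects, and treating it
as negative poisons the regression target.  `pulocalize` implements a
positive–unlabeled (PU) learning pipeline that trains a localizer from
exactly this kind of sparse point annotation.

## The redundant count map

A point annotation set is rasterized into a binary *location map*
$P_{gt}$ with a unit impulse at each object center.  The training
target is not a smoothed density but the *redundant count map*

$$C(i,j) \;=\; \sum_{(m,n)\in S_r(i,j)} P(m,n),$$

the sum of the location map over the $r\times r$ square window centered
at each pixel ($r$ odd, windows clipped at the image border;
`make_count_map()`).  Each annotated point inflates into an $r^2$-pixel
block of non-zero counts, which rebalances positives versus background
by a factor of $r^2$ — the imbalance is what breaks naive pixel-wise
classification in this regime.  Because the operator is linear and
(for objects farther apart than the kernel) injective on impulse maps,
the non-negative minimizer of
$\sum_{i,j}\big((B_rP)(i,j) - C_{gt}(i,j)\big)^2$ is the impulse map
itself: a model trained to reproduce count maps is implicitly trained
to produce sharp local maxima at object centers.
`recover_location_map()` demonstrates this numerically by accelerated
projected gradient descent; the package's tests verify that the 5×5
single-target toy problem recovers the exact delta map to $10^{-4}$.

The kernel should be *slightly smaller* than the smallest object
diameter: big enough to rebalance the classes, small enough that no
window covers two objects.  `count_map_config()` therefore warns, but
does not refuse, when $r$ reaches the declared minimal diameter —
kernel choice is a judgment call that depends on the object-size
distribution.

## Non-negative PU risk

Let $\tilde C_{gt}$ be the count map of the *provided* (partial)
annotations, $M$ its non-zero indicator ("positive mask", $N_p$ ones),
and $C_{pre}$ the count map of the predicted location map.  The loss is
the non-negative PU risk

$$\hat R_{pu} \;=\; \pi_p\,\hat R_p^+ \;+\;
  \max\!\big(0,\; \hat R_u^- - \pi_p\,\hat R_p^-\big),$$

with an L2 positive risk
$\hat R_p^+ = \frac{1}{N_p}\lVert (C_{pre}-\tilde C_{gt})\odot
M\rVert_F^2$ and a tanh-suppressed negative part
$\hat R_u^- - \pi_p \hat R_p^- = \frac{1}{N}\sum \tanh C_{pre} -
\frac{\pi_p}{N_p}\sum \tanh(C_{pre}) M$
(`nonneg_pu_risk()`).  The debiasing by the class prior $\pi_p$ is what
lets the *entire* training set serve as the unlabeled sample — the risk
does not require positives and unlabeled data to be independent.  The
clamp at zero is the standard guard against a flexible model driving
the estimated negative risk negative (i.e., overfitting the unlabeled
region); when it engages, the clamped term contributes zero gradient.
The prior can be estimated from scene statistics as
$\pi_p \approx \mu r^2/(\omega h)$ (`estimate_class_prior()`), but a
fixed $\pi_p = 0.1$ is used for training by default: it is the right
order of magnitude across the dense-object regimes this package
targets, and a fixed value avoids per-dataset tuning.

## Pseudo-labeling with a beta mixture

After PU training, unlabeled count-map entries with a confident
prediction can be promoted to pseudo-labels.  The negative loss of an
unlabeled entry is $l_{ij} = C_{pre}(i,j)^2$ where
$\tilde C_{gt}(i,j)=0$: small where the model agrees the entry is
background, large where the model insists on an object the annotations
missed.  Entries with $l < 0.01$ are *clear negatives* and are removed
before modeling, since their overwhelming number would otherwise
dominate the fit.  The surviving losses are mapped affinely onto
$(\epsilon, 1-\epsilon)$ (min–max over survivors, $\epsilon = 10^{-4}$;
the bounds are stored so any raw loss can be queried later) and modeled
as a two-component beta mixture

$$p(l) = \textstyle\sum_{k=1}^{2} \lambda_k\,
  \mathrm{Beta}(l \mid \alpha_k, \beta_k),$$

fitted by EM (`fit_bmm_em()`): log-space E-step, mixing weights from
mean responsibilities, shapes by weighted maximum likelihood started
from weighted method-of-moments estimates.  Because the shape update
never accepts a candidate with lower weighted likelihood than the
current shapes, each iteration is a generalized EM step and the
observed-data log-likelihood is non-decreasing — plain moment updates
(`m_step = "moments"`) are faster but can overshoot the likelihood
near convergence.  Initialization splits the data at the median and
moment-fits each half, so the fit is deterministic given the data; the
seed only drives a single re-initialization if a component collapses.
On unimodal (all-background) loss sets the two components legitimately
overlap on the low cluster — the weight split between near-identical
components is arbitrary, but no appreciable mass lands at high loss
and peak posteriors stay away from both thresholds, so no false labels
are produced.

The posterior $p(k{=}2\mid l)$ (`posterior_noisy()`) scores every local
maximum of the predicted location map.  Peaks with posterior
$\ge \tau_{pos}$ become predicted positives, peaks with posterior
$\le \tau_{neg}$ and all non-peak unlabeled coordinates predicted
negatives; peaks in between are ignored.  The defaults
$\tau_{pos} = 0.95$, $\tau_{neg} = 0.05$ are deliberately conservative:
an injected false positive label does more damage than an ignored true
one.  Provided annotations always win — a peak on or within
$\lceil r/2\rceil$ of a provided positive is absorbed into the provided
set rather than double-counted.  The refinement loss is then an
ordinary positive–negative L2–tanh objective

$$L = \frac{1}{N}\Big(\sum_{\Phi^+}(C_{pre}-1)^2 +
  \sum_{\Phi^-}\tanh C_{pre}\Big),$$

with count target 1 on positives: the kernel is smaller than an
object, so a positive window covers exactly one object.

## The predictor

Any encoder–decoder that outputs a non-negative map at input resolution
fits the contract (`predict_location_map()`).  The built-in model is a
small two-level U-style network — two 3×3 conv+ReLU blocks, 2× average
pooling, two blocks at half resolution, nearest upsampling with a skip
concatenation, a fusing block, and a 1×1 conv with ReLU output (the
output ReLU is what enforces non-negativity).  Convolutions are lowered
to im2col + BLAS matrix products in compiled code; gradients are
hand-derived and verified against finite differences in the test suite.
`base_channels` (default 8) sets the width; the synthetic benchmark
preset uses 6, which saturates the disk-detection task in a few
thousand parameters and trains within a CPU-only budget.  Real
micrographs with texture and staining variation would warrant a wider
or deeper model — the width is a config knob, not a constant.

## Two-stage schedule

Stage 1 (PU): per epoch, each annotated image contributes one Adam step
on a batch of $4n$ images: $n$ positives, $n$ randomly rotated/flipped
copies of them (annotations transformed along; rotations are skipped
for non-square images), and $2n$ images drawn from the whole training
set as unlabeled data.  Each epoch also resamples 2/3 of every image's
annotations when building $\tilde C_{gt}$, a cheap regularizer that
prevents the model from latching onto the specific annotated subset.
Validation F1 (peak detection + greedy matching on fully annotated
validation scenes) is computed only after a 20-epoch delay — early maps
are noise and peak search on them is wasted work — and the
best-validation weights are kept.  The learning rate starts at
$10^{-4}$, scaled linearly by batch size over 8 for the small batches
used here, and halves after 10 evaluated epochs without improvement.

Stage 2 (refinement) starts from the best stage-1 weights at a rate 100
times smaller.  Each epoch recomputes predictions for all training
images, pools the unlabeled losses across images, refits the beta
mixture (pooling stabilizes EM; per-step refits would fit to minibatch
noise), partitions every image, and steps on the PN loss over plain
image minibatches.  Refinement batches drop the positive/augmented
composition of stage 1 — the PN loss has labels everywhere, so the
batch balancing that PU learning needs serves no purpose here — and the
provided labels enter $\Phi_p$ unthinned.  Validation selection
includes the stage-1 initialization as epoch 0, so refinement never
returns weights that score worse than its starting point on the
validation data.  Model selection uses fully annotated validation
scenes: measuring a true F1 requires true centers, and a handful of
fully annotated validation images is the cheap part of the labeling
budget.

## Evaluation

A prediction is a true positive when it pairs one-to-one with a ground
truth center within a distance threshold (6 px is the histopathology
convention; animal datasets use the minimal object radius; the packaged
benchmark uses 4 px ≈ the disk radius).  Matching is greedy
nearest-first over the sorted within-threshold pairs — deterministic,
with (distance, gt, pred) tie-breaks.  Greedy matching can in rare
blocking configurations lose one match relative to the exhaustive
maximum-cardinality optimum (about 0.1% of random small instances);
an exhaustive optimal matcher (`method = "optimal"`) is provided for
sensitivity checks.  `mean_localization_error()` averages matched
distances and charges every unmatched point a penalty distance; the
penalty convention varies between published protocols, so it is
exposed (default: the matching threshold).

Peak extraction (`find_peaks()`) takes local maxima over $r\times r$
Chebyshev neighborhoods (square windows, matching the kernel geometry)
above a scale-free threshold of 0.1× the map maximum, resolving
plateau ties to the smallest coordinate.  `peak_prominence_stats()`
compares peak heights against the central density $1/(2\pi\sigma^2)$
of a unit-mass Gaussian with $\sigma = r/6$ (the Gaussian whose
$\pm 3\sigma$ support matches the kernel): count-map training pushes
each object's peak above that baseline (the margin grows the longer
training concentrates the mass), which is the practical reason the
local-maximum read-out is reliable.

## The synthetic benchmark

`generate_scene()` renders soft-edged disks (1-pixel anti-aliased rim)
on a darker background with additive Gaussian noise — the geometry of
small round objects (nuclei, droplet-encapsulated cells) without
texture modeling.  Defaults define the packaged benchmark: 96×96 px,
15 ± 2 disks of radius 4 at pairwise center distance ≥ 9 (disjoint
disks), contrast 0.7 over a 0.1 background, noise SD 0.02, and a
*single* labeled point per training image — about 7% of the
annotations.  `run_benchmark()` generates 48 training, 8 validation
and 16 test scenes, trains both stages (kernel 7, prior 0.1), and
scores test F1 at 4 px.  The preset trains 25 stage-1 and 5 stage-2
epochs with a width-6 predictor: the trajectory on these small
homogeneous scenes plateaus well before the 100-epoch schedule that
full-size heterogeneous datasets need, and the run completes in a few
minutes on one CPU core.

What passing this benchmark does and does not show: it shows the full
mechanism works end to end — a localizer trained with one click per
image finds ~15 objects per test image with high F1, and the
pseudo-label stage never degrades the stage-1 solution.  It does not
exercise texture, staining variation, perspective scaling, overlapping
objects, or annotation jitter; on such data the synthetic numbers are
an upper bound on what this recipe would deliver.  On these saturated
synthetic scenes stage 2 typically confirms rather than improves the
stage-1 solution (its published gains, fractions of a percent to a few
percent, come from harder datasets with more headroom).

## Numerical choices and degenerate inputs

* Count-map windows are clipped at borders (no padding); for the box
  kernel this equals zero padding exactly, preserves non-negativity,
  and keeps interior mass conservation $\sum C = r^2 \cdot$ (number of
  interior targets).
* Coordinates are 0-based (row, col) externally (CSV, peak tables);
  fractional annotations rasterize to the nearest pixel with ties
  toward the smaller index.
* A batch with no positive entries raises a typed condition; the
  trainer skips the step.  An empty survivor set after clear-negative
  removal skips pseudo-labeling for that round (all peaks then default
  to predicted negatives).
* The clamped PU risk has a degenerate stationary point at the
  all-zero location map (risk $= \pi_p$ exactly), and a fraction of
  weight initializations slide into it within a few epochs.  Three
  guards keep training out of it: interior activations are leaky
  ReLUs (slope 0.01), so features cannot die outright; the output
  ReLU is exact in predictions but the trainer backpropagates a 1%
  leak on its clamped side, so a transiently all-negative head can be
  pulled back by the positive-sample loss; and stage 1 probes the
  predicted map at epochs 6 and 10 — if its maximum has fallen below
  0.01 the run restarts from a fresh initialization (up to four
  restarts, with all candidate seeds pre-drawn from the master seed so
  the procedure stays deterministic).
* `recover_location_map()` uses FISTA with step $1/(2r^4)$, a safe
  bound on the Lipschitz constant of the box-sum normal operator.
* EM stops on absolute log-likelihood change $< 10^{-6}$; beta shapes
  are clamped to $[10^{-3}, 10^4]$; densities and posteriors are
  evaluated in log space throughout.
* Training is single-threaded and fully deterministic given the master
  seed, which fans out to scene generation, weight init, annotation
  resampling, augmentation and batch order.

## Limitations

* The matcher's greedy optimum gap (above) is negligible for scoring
  but means F1 is not invariant to adversarial point configurations.
* The BMM stage assumes hidden positives produce *large* squared
  counts; a stage-1 model that underfits everywhere gives a unimodal
  loss distribution and stage 2 then (correctly, conservatively) finds
  nothing to promote.
* `optimal` matching is exhaustive and limited to 8 points per side;
  it is a verification tool, not a scoring path for dense scenes.
* Checkpoints are RDS files (weights + config), not portable across
  incompatible package versions.
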