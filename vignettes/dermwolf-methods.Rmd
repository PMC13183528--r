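---
title: "Methods: gray wolf optimization for dermoscopic melanoma analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gray wolf optimization for dermoscopic melanoma analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dermwolf implements a hybrid analysis stack for dermoscopic melanoma
detection: an improved gray wolf optimizer (IGWO) with fitness-based omega
regeneration, image conditioning (Gaussian denoising, DullRazor hair
removal, lookup-table contrast stretching), Kapur-entropy multilevel
thresholding with the optimizer in the loop, and a compact convolutional
network trained under a class-weighted protocol with patient-grouped
splits. Everything is exercised end to end on a seeded synthetic
dermoscopy generator, so the full pipeline is testable on one CPU with no
external data. This vignette records the models, the tunable parameters,
and the design decisions taken where the method description left genuine
freedom.

## The gray wolf optimizer and the improved variant

Canonical GWO maintains `N` agents in a box-bounded space and, each
iteration, pulls every agent toward the three best solutions found so far
(alpha, beta, delta). For agent `x` and elite `e` the pull is

    D_e = | C * e - x |,      X_e = e - A * D_e,

with the agent moving to the mean of the three `X_e`. The coefficient
vectors are `A = 2 a r1 - a` and `C = 2 r2`, with `r1`, `r2` uniform on
[0, 1] drawn fresh per agent and per dimension, and the control scalar
`a = 2 (1 - t / T)` decaying linearly from 2 to 0. One `(r1, r2)` pair per
agent per dimension is shared across the three elite pulls; the three
distances use the same `C` and the three candidate positions the same `A`.
The shared-coefficient form is the one under which the improved variant's
advantage materializes in our experiments — with independent draws per
elite the averaging in the final step cancels most of the perturbation and
the plain optimizer is already near its fixed point.

IGWO adds *fitness-based omega regeneration*. After each evaluation sweep
the agents are ranked; the worst `floor(r N)` (default `r = 0.3`, so 9 of
30 agents — never touching the three best) are eliminated and replaced:

* with probability `p = 0.7`, by an exact copy of one elite, drawn with
  probability proportional to the rank weights 3:2:1 for
  alpha:beta:delta;
* otherwise by a Gaussian probe around the leader,
  `x_alpha + sigma * g`, `g ~ N(0, I)`, with `sigma = 1/(t + 1)` so the
  probes tighten hyperbolically over the run.

Two details are deliberate design decisions:

* **Ordering.** Regeneration happens before the pack move. Elite copies
  join the move immediately, which turns them into an intensified local
  search around the leaders. Gaussian probes, however, would be destroyed
  by the move (the pull term `|C e - x|` scales with the elite's
  coordinate magnitude, so a freshly placed probe would be flung far from
  where the decaying sigma put it). During the first half of the run the
  probes therefore join the move like any other wolf — wide exploration
  is still wanted — and during the second half they are evaluated exactly
  where they were placed, acting as a fine-grained refinement of alpha.
  This realizes the stated intent of the mechanism: exploitation is
  enhanced without compromising exploration, especially in later
  iterations. Simpler orderings each break one documented property
  (either the multimodal-benchmark advantage over canonical GWO, or the
  ability to resolve a continuous hyperparameter to two decimals).
* **Greedy memory.** An agent only keeps a move that improves its own
  best-known fitness; a regenerated agent always adopts its replacement
  (its memory is reset), otherwise elimination would be vetoed by the
  agent's own history. The canonical GWO variant (`variant = "gwo"`) is
  non-greedy and never regenerates, as in its standard description.

Other conventions: minimization throughout (callers negate maximization
objectives); out-of-box proposals are clipped to the bounds; integer
dimensions are rounded to the nearest integer before every evaluation and
after every move; fitness ties are broken by agent index; `p` is taken
from the formal method description (0.7) rather than the 50% mentioned in
passing elsewhere, and is configurable.

## Preprocessing

Dermoscopic images carry sensor noise, hair/ruler artifacts and often low
contrast. The conditioning chain is denoise, then hair removal, then
contrast stretch.

* **Gaussian denoising** convolves each channel with a normalized discrete
  Gaussian (truncated at 3 sigma, replicated borders; EBImage's `filter2`
  does the convolution). The default `sigma = 0.5` is deliberately light:
  it suppresses pixel noise below the hair detector's threshold while
  barely moving the lesion boundary. Heavier smoothing (sigma around 1)
  measurably biases the Kapur threshold toward the background mode by
  populating the intensity gap with mixed boundary pixels, which costs
  about 5 IoU points on synthetic lesions.
* **DullRazor hair removal** detects thin dark structures by grayscale
  morphological closing (dilate then erode, square element, default 7×7 —
  the element must exceed the hair width while staying small relative to
  the lesion, so the pipeline's desk profile uses a 3×3 element at its
  32-px image size; a 7-px element there erases the thin border arms of
  irregular lesions, the very feature that distinguishes the malignant
  class): the closing erases structures
  thinner than the element, so the absolute difference against the
  original lights up exactly there. The difference is thresholded (default
  10 intensity levels), the raw mask is cleaned by a 3×3 opening, connected
  components smaller than 15 px are discarded (hair strokes are hundreds
  of pixels long; noise clusters are tiny), and the mask is grown by two
  3×3 dilations to cover anti-aliased stroke borders. Masked pixels are
  replaced by the closed image's values (default) or by the median of
  unmasked neighbors ("median" mode). Pixels outside the returned mask are
  never touched, and an image with no detections is returned bit-identical.
  The detector is calibrated to run after denoising: on raw noisy images
  the lesion rim itself can exceed the closing threshold.
* **Contrast stretching** maps each channel's observed minimum to 0 and
  maximum to 255 through a 256-entry lookup table,
  `out = round(255 (v - min)/(max - min))` with round-half-up
  (`floor(x + 0.5)`) for cross-platform determinism. The printed density
  formula in the method source is typographically corrupted (identical
  terms in offset and denominator); the min–max stretch is the only
  reading consistent with an 8-bit lookup-table enhancement and with the
  shown example behavior. Constant channels pass through unchanged, and
  the operation is idempotent.

## Kapur-entropy segmentation

For an intensity histogram `ph` over 256 levels and sorted thresholds
`th_1 < ... < th_{m-1}`, class `j` covers `[th_{j-1}, th_j)` (a pixel equal
to a threshold goes to the upper class) and contributes its within-class
Shannon entropy

    H_j = - sum_{i in class j} (ph_i / w_j) ln(ph_i / w_j),

`w_j` the class mass; the objective `J = sum_j H_j` is maximized. The
printed formula omits the minus sign of standard Kapur entropy; it is
restored so that `J >= 0` and maximization is meaningful (the source
itself maximizes `J`). Empty bins and empty classes contribute zero. The
implementation evaluates whole candidate populations at once from two
cumulative tables, so one evaluation is O(m).

`find_thresholds()` minimizes `-J` with IGWO over integer thresholds in
1..254, repeats the run 25 times (the protocol's repeat count) under
distinct sub-seeds, and reports the per-position mean of the sorted
per-run vectors, rounded; rounding collisions are resolved by
incrementing, with a message. This averaging is the only coherent reading
of "repeat and take the mean as the optimal threshold".
`exhaustive_thresholds()` provides the brute-force optimum for m = 2 (254
candidates) and m = 3 (about 32k pairs) as an independent optimality
reference; on bimodal and trimodal synthetic histograms the optimizer
attains it exactly.

`segment_lesion()` takes the darkest class as foreground (melanocytic
lesions are darker than surrounding skin; `foreground = "bright"` inverts
the image and reuses the same path, so results mirror exactly), then
cleans the mask: fill holes, open, close — in the order the operations are
introduced in the method description — with a 3×3 box element, and keeps
the largest 8-connected component. Hole filling iterates the geodesic
dilation `X_k = dilate(X_{k-1}, e) & !A` from a border-seeded background
marker to its fixed point, so background touching the border is never
filled; with the 3×3 box this walks the background with 8-connectivity.
Binary dilation treats the outside as background and erosion as
foreground, making opening and closing exact complement-duals everywhere
including borders. Connected components are 8-connected (diagonal-merged
on top of EBImage's 4-connected labeling).

## The classifier

The network is fixed apart from its searched hyperparameters: three blocks
of {3×3 same-padding convolution with `f_i` filters, ReLU, 2×2 max-pool
with floor division}, then flatten, a 128-unit ReLU dense layer, dropout
`d`, and a 2-way softmax. Padding is "same" (the description never states
it; the printed total parameter count is not reconcilable with any
standard convention, so the count is defined by the closed form
`sum_i (9 c_in f_i + f_i) + flat*128 + 128 + 128*2 + 2` instead). The
mention of "filter sizes 32×32, 64×64, 128×128" is read as filter counts
32/64/128 with 3×3 kernels, following the explicit replication section.

Training minimizes class-weighted categorical cross-entropy — weights
`w_c = n/(2 n_c)`, inversely proportional to class frequency, so the
weighted sample mean is 1 — with RMSprop (learning rate 0.001, rho 0.9,
epsilon 1e-7), batches of 32, up to 50 epochs, early-stopped on validation
loss with patience 10 and restoration of the best-validation weights. An
optional L2 penalty `wp/2 * sum(W^2)` over weight matrices is available
(`wp = 0` reduces exactly to the plain loss). The separate squared-error
measure `E = (1/T) sum_i sum_j (f_ji - y_ji)^2` is provided as a quality
metric, not as the training loss — the protocol names cross-entropy as the
loss. Dropout is inverted (scaled at train time), applied between the two
dense layers.

Because no deep-learning framework is part of the package's dependency
set, the forward and backward passes are implemented directly:
convolutions are lowered to BLAS matrix products over im2col patch
matrices with activations kept in an (H, W, batch, channel) layout so the
lowering is a plain reshape. The gradients are verified against central
finite differences (relative error ~1e-7) in the test suite, and He
initialization is used for all ReLU layers.

**Desk scaling.** The reference protocol's learning rate (0.001) is tuned
for tens of thousands of gradient steps. The package's desk profile —
250 synthetic images at 32×32, 6 mini-batches per epoch, 10 epochs — takes
only ~60 steps, over which that rate cannot move the weights far enough to
fit even a separable problem. The desk profile therefore uses 0.005
(0.01 destabilizes early stopping for some seeds); the paper profile keeps
0.001 alongside 225×225 inputs and 50 epochs. This is a scaling choice,
fixed once, and recorded here.

Data handling is patient-grouped everywhere: `split_dataset()` assigns
whole patients to train/validation/test (70/15/15 by default), greedily
filling per-class image targets so both totals and the malignant fraction
are preserved to within patient granularity, and `kfold_patient()` builds
class-stratified 5-fold partitions the same way. No patient identifier
ever straddles subsets.

## Hyperparameter search

The search space is exactly the four exposed quantities: three integer
filter counts in [16, 256] and a continuous dropout in [0.2, 0.8]. The
objective is the validation loss of the candidate network trained under
the fixed protocol; candidates are cached on their decoded values, so
elite copies cost nothing. Dropout is evaluated un-rounded. The fitness
subset is a patient-grouped stratified 15% of the training patients, fixed
once per search. The optimizer runs with 30 agents; the reference budget
of 200 iterations is kept for the surrogate demonstrations (cheap
objective), while searches that actually train networks default to a small
desk budget (`max_iter = 10`) and scale up via configuration. On the
quadratic surrogate with optimum (32, 64, 128, 0.54) the search recovers
the integer triple exactly and the dropout to within 0.01 in 25 of 25
seeds at the reference budget.

## The synthetic dermoscopy generator

The generator emulates the salient structure of public melanoma screening
data: two-class lesion images with strong class imbalance, hair artifacts,
reduced contrast, and patient grouping for leakage-free evaluation. A
lesion is a rotated ellipse whose radius is perturbed by a low-order
Fourier series (harmonics 3–8) for border irregularity plus 1st/2nd
harmonic lobes for asymmetry, rasterized with an anti-aliased ~1.5 px
edge; the exact mask (coverage >= 0.5) is returned as ground truth.
Malignant-like lesions differ from benign-like ones geometrically (high
irregularity and asymmetry) and in texture (higher intra-lesion variance
and dark pigment blotches) — not in mean intensity alone — so a classifier
must learn shape and texture rather than a brightness threshold. Hair is
composited as dark anti-aliased Bezier arcs with exact stroke masks.
Labels are assigned to image slots (a patient may carry both classes, as
in screening practice), the malignant count is exactly
`round(n * imbalance)`, and every record is generated under a sub-seed
derived from (manifest seed, record index), so regeneration is
byte-identical.

What the generator does *not* emulate: real pigment-network texture, ruler
marks and gel bubbles, illumination fields, camera color profiles, or skin
tones. Tests passing on this generator demonstrate that the machinery —
optimization, detection, segmentation, leakage-free training — works as
specified; they say nothing about clinical performance on real
dermoscopy, which the reference protocol evaluates on an external dataset
at GPU scale.

Test problem sizes, chosen to exercise the stated protocol strengths while
staying CPU-friendly: Kapur optimality on three 63×63 synthetic histograms
(m = 2 and 3, 25 repeats, 25 seeds); benchmarks at dimension 10 with 30
agents and 200 iterations, 25 paired seeds; segmentation on twenty 128×128
lesions; the end-to-end run on 250 images at 32×32 over 50 patients.

## Known limitations

* Kapur thresholding with m = 2 places the threshold at the entropy
  optimum, which for heavily imbalanced class masses is not the histogram
  valley; strongly blurred inputs shift it further. The light-denoising
  default mitigates this; heavily degraded real images may need m = 3.
* The CNN is trained in plain R; it is fast at desk scale (seconds per
  epoch) but not intended for 225×225 full-scale training, which the
  paper profile merely parameterizes.
* The morphological hole filler is exact but iterative (one dilation per
  front step); for very large masks a scanline fill would be faster.
* Training at very small sample sizes is bimodal — a run either learns the
  minority class or collapses to the majority; class weighting makes the
  learning mode much more frequent but the variance is inherent to 60-step
  training runs.
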