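---
title: "Methods: contour-based segmentation and liveweight regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour-based segmentation and liveweight regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models, the
supervision theory, the synthetic benchmark, and the numerical and design
choices a maintainer would want explained. Nothing here states an
empirical result that the test suite does not itself compute.

## Problem setting

Estimating the body weight of group-housed animals from a ceiling camera
without touching them requires two steps: find each animal's dorsal
outline in the frame, and map that outline to kilograms. Both steps have a
twist. Segmentation-quality outlines are usually produced as pixel masks,
which are expensive to compute and awkward to feed to a downstream
regressor; and the mapping from an *image* outline to weight is ill-posed
unless the regressor can compensate for where the animal stands, because
perspective makes the same animal appear larger or smaller across the
pen. The package's two networks address exactly these points: the contour
network outputs coordinates rather than masks, and the weight network
receives normalized coordinates that carry both absolute position and
pure shape.

## The contour network

**Feature extraction.** A strided convolutional backbone produces maps at
strides 4, 8, 16 and 32; iterative deep aggregation fuses them pairwise,
`T(o1, ..., on) = T(N(o1, o2), ..., on)`, into a stride-4, 24-channel map
`F`. Each aggregation node projects both inputs to 24 channels with 1x1
convolutions, upsamples the deeper map (nearest-neighbour), sums, and
applies a 3x3 convolution with ReLU. The aggregation-node internals are
not pinned down by the architecture's public description; this minimal
node (project-sum-convolve) is the package's documented default. The
full-scale backbone in the original design is a MobileNetV2 prefix; this
package ships a plain-convolution backbone with the same stride pattern
and configurable widths, because the stride pattern — not the specific
inverted-residual blocks — is what the rest of the architecture depends
on. The `"paper"` preset uses widths 24/32/96/320, the `"desk"` preset
16/24/32/48 on 96 x 96 inputs.

**Initialization.** Two heads on `F` predict a sigmoid center heatmap and
a regression map with `2N` channels; reading the regression vector at a
center cell and adding the center coordinates yields an `N`-vertex initial
contour in one step. During training centers come from ground truth;
at test time 3x3 local maxima of the heatmap above a threshold (default
0.3, configurable — the value is not architecture-determined) become
centers, with the peak value as the detection score.

**Refinement (CSA).** For each vertex, a 254-channel (desk: 30-channel)
feature is sampled bilinearly from a refined map `F'` (two 3x3
convolutions on `F`; "several convolution layers" is unquantified, so the
smallest stack giving the stated channel count is used) and concatenated
with the vertex's box-normalized coordinates — the contour positional
embedding. The resulting `N x (254+2)` sequence passes through multi-head
self-attention,

    MHSA(P) = P + (ReLU(P + Attention(P)) Wz1) Wz2

with 8 heads (desk: 4) and the feed-forward matrices `d x 4d` and
`4d x d`. Note the formulation as printed places the ReLU on the residual
sum and stacks the two feed-forward matrices without an inner activation;
the package implements it verbatim. A single linear map `d -> 2` turns
each output row into a vertex offset (the reduction from `d` to 2 is not
specified in the source architecture; one bare linear head is the minimal
choice, and it is zero-initialized so refinement starts as the identity).
Two CSA blocks run in sequence with unshared weights (sharing is
unspecified; unshared is the more general default).

## Supervision: soft versus hard assignment

A predicted contour and a ground-truth contour are both point sets; the
question is what "distance between them" the training signal should
minimize.

**HardAssign** matches points one-to-one with the Kuhn-Munkres algorithm
on the Euclidean cost matrix and penalizes matched pairs with smooth-L1
(the transition point is 1 feature-pixel; the baseline's pair loss is not
specified in the source, and smooth-L1 matches the regression losses used
elsewhere in the design).

**SoftAssign** treats both sets as uniform discrete measures and uses the
debiased Sinkhorn divergence

    L_OT = OT_eps(alpha, beta) - OT_eps(alpha, alpha)/2 - OT_eps(beta, beta)/2

with unsquared Euclidean ground cost. The entropic term OT_eps is solved
in its dual form by log-domain Sinkhorn iterations with Jacobi-style
averaged updates (numerically stable at small epsilon, and exactly
symmetric under swapping the arguments). Epsilon anneals geometrically
from the point-cloud diameter (a scale-free "large initial estimate") to
the target 0.05 with ratio 0.5. Position gradients use the converged dual
potentials directly: the gradient at each predicted point is a
softmax-weighted average of unit vectors toward the target points minus
the analogous self-term, scaled by the point's mass. Coincident points
contribute a zero direction vector (a subgradient choice that avoids NaN
in a measure-zero event). The analytic gradients are verified three ways
in the test suite: against central finite differences, and against
complex-step differentiation *through the solver iterations themselves*,
which differentiates the actual computational graph to machine precision.

**Units.** Before the OT loss, coordinates are divided by the feature-map
size so that epsilon = 0.05 has one meaning across image sizes. The
resulting divergence is then rescaled by the map size back to
feature-pixel units. This matters for the total loss

    L = L_focal + 0.5 L_init + 0.5 L_csa1 + 1.0 L_csa2,

whose stage weights are fixed constants: the KM baseline's smooth-L1
lives in feature pixels, so the OT alternative must be expressed in the
same cost units for the supervision comparison (and the fixed weights) to
be meaningful.

**Heatmap loss.** The center heatmap is trained with the penalty-reduced
focal loss from the center-point detection literature: peak pixels
contribute `(1-p)^2 log p`, all others `(1-t)^4 p^2 log(1-p)`, normalized
by object count. The target construction (not specified beyond the loss
name) is a Gaussian splat per instance with sigma proportional to the
instance radius at feature resolution (radius/3, floored at 1 cell).

**Backpropagation through refinement.** Vertex positions entering a CSA
block are treated as fixed for the purposes of feature sampling and the
positional embedding (stop-gradient); each stage's own loss term
supervises the contour it receives, so every parameter still receives
gradient through its stage loss while the implementation avoids
differentiating the bilinear sampler with respect to its sampling
positions. This deep-supervision reading is consistent with the total
loss above, which attaches a loss to every stage.

## The weight network

The N x 2 contour is normalized two ways and concatenated into an N x 4
sequence: image normalization `(x - W)/W, (y - H)/H` (as printed, this
maps into [-1, 0]; a centered alternative is available behind a config
flag, but the printed form is the default — fidelity over plausibility),
and box normalization, which rescales the contour into its own bounding
box and acts as the positional embedding. After a linear projection to
d_hide = 512, one MHSA block, mean pooling over positions, and a
512 -> 128 -> 1 LeakyReLU head, the output is the liveweight in kg with
no output activation. Biases are included on the projection and head
layers and omitted inside attention (the printed equations show bare
matrices there); the trainable-parameter count is 3,214,081, formatting
to "3.2M". Mean pooling over attention outputs makes the prediction
exactly invariant to vertex order, so the network accepts ordered or
unordered contours.

Training uses smooth-L1 on internally standardized targets (the output
layer maps back to kg; standardization only conditions the optimization),
Adam with weight decay 5e-4, a 10-epoch warm-up at 0.1x, and 10x decay at
epochs 80/160/240/320 over 400 epochs at full scale. Augmentation:
uniform resampling of N points from a 4N-point oversampling of the
ground-truth boundary with random phase, horizontal flips, and Gaussian
coordinate jitter (sigma = 0.5 px; the magnitude is unspecified in the
source and configurable here).

## The synthetic benchmark

The generator emulates the structure of an annotated pig-pen dataset
without any of its pixels. Each synthetic animal is a closed outline:
ellipse body (semi-axes a in [4.0, 6.8] world units, aspect b/a in
[0.42, 0.58]), a cosine-windowed head bump (8-18 % amplitude), and a
gentle quadratic spine bend; bend and rotation are area-preserving shear
and rigid maps, so an animal's world area is a stable property across
sightings. A camera model scales the outline by a position-dependent
factor (1.15 at the pen center falling linearly to 0.85 at the corners,
at 3 px per world unit for 96 x 96 desk scenes) — the same animal appears
up to ~35 % larger in area depending on where it stands. Liveweight is
`k * area^p * (1 + e)` with k = 1.35 kg per unit area, p = 1 and
e ~ N(0, 0.02^2), yielding weights spanning roughly 30-115 kg, the growth
range of a finishing pig. Weight depends on *world* area, so an estimator
seeing only the projected contour must exploit image position — the
property the weight network's image-normalization columns exist for. A
back area roughly proportional to liveweight (p = 1) is a reasonable
local approximation over this growth range and keeps the benchmark's
difficulty in the mapping, not in an arbitrary exponent.

Scenes place 1-2 animals (desk) without overlap by rejection sampling on
bounding radii; animals are assigned to train/validation/test first and
scenes are generated within splits, so no animal's geometry leaks across
splits. Rendering is deliberately plain (flat floor, tinted body fill,
Gaussian pixel noise): the benchmark probes the geometry pathway, not
photometric robustness. Passing tests on it therefore show that the
*mechanisms* work — supervision, refinement, normalization, evaluation —
not that the networks would segment real barn imagery, which has
occlusion, lighting variation and breed diversity the generator does not
model.

## Study conditions and problem sizes

Chosen once as the package's CPU-scale conditions:

* **Contour network benchmark**: 200 scenes (100/50/50), 96 x 96 px,
  N = 32 vertices, 14 epochs (Adam 1e-3, decay 0.3 at epochs 8 and 12,
  batch 1), both supervision variants trained at the identical budget and
  seed. Mask AP is computed on rasterized TSP-ordered predictions against
  rasterized ground truth at COCO thresholds.
* **Weight network benchmark**: 2,000 training contours from a 600-animal
  pool (large enough that the held-out animals form a meaningful
  generalization set), 2 % weight noise, desk configuration (48 points,
  d_hide 64, 4 heads, 40 epochs). The noise level alone bounds attainable
  R² near 0.994; the acceptance threshold of 0.95 leaves room for model
  error.
* Sinkhorn: training tolerance 1e-5 on the potential update (max 120
  iterations at the final epsilon); verification tests run to 1e-13. The
  solver raises an error when the residual is more than 1e-3 of the mean
  cost — in stochastic training a slightly loose solve is harmless, a
  genuinely unconverged one is not.

## Numerical choices and degenerate inputs

* Box normalization errors on zero extent rather than emitting NaN;
  callers must filter sub-pixel instances.
* Greedy TSP breaks nearest-neighbour ties by lowest point index and adds
  the input ordering to the candidate tours; the selection criterion is
  minimal closed-tour length, the only truth-free criterion consistent
  with the TSP framing (the original description selects by contour
  accuracy, which requires ground truth unavailable at inference).
* Rasterization is even-odd scanline at pixel centers (0-based,
  pixel-center convention, implicit polygon closure); self-intersecting
  polygons rasterize even-odd with a warning.
* The duplicate-frame filter compares each frame to the last *retained*
  frame by default, so a slow drift is not collapsed forever; the
  raw-adjacent alternative is a flag. The DCT is the orthonormal type-II
  transform on a bilinear 32 x 32 resize of the BT.601 luma; the strict
  inequality (bit = 1 only when the coefficient exceeds the block mean,
  which includes the DC term) follows the printed rule exactly.
* Hard assignment uses an O(n^3) shortest-augmenting-path Kuhn-Munkres
  solver, verified against exhaustive permutation up to n = 7.
* All randomness (weights, data order, sampling phases, augmentation,
  noise) flows from a single seed per run; identical seeds reproduce
  training losses bit-for-bit.

## Known limitations

* The backbone is not a faithful MobileNetV2; transfer of full-scale
  hyperparameters to real data is untested by construction (no real data
  ships with the package).
* The synthetic benchmark contains no occlusion or touching animals, so
  the evaluation never exercises mask disambiguation between overlapping
  instances.
* The "paper" preset encodes the full-scale schedules but running it to
  convergence on real imagery is outside CPU reach; it exists so the
  configuration is inspectable and the architecture constructible at full
  width.
* Timing figures (frames per second) are hardware-bound and are logged
  nowhere; no test asserts throughput.
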