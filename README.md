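# contourweight

Non-contact liveweight estimation for group-housed livestock from overhead
RGB images, via a dual-network design: a **contour information extraction
network (CIEN)** that regresses and refines per-animal boundary polygons
instead of pixel masks, and a **liveweight estimation network (LWEN)** that
regresses body weight in kilograms directly from the N contour coordinates.
The package is written for researchers in precision-livestock imaging who
want every component of such a pipeline — dataset filtering, contour
supervision, attention-based refinement, weight regression, evaluation —
runnable and testable on a single CPU, with a deterministic synthetic scene
generator standing in for farm data.

## The models

**CIEN.** A strided convolutional backbone emits feature maps at strides
4/8/16/32, fused by iterative deep aggregation,
T(o₁,…,oₙ) = o₁ if n = 1, else T(N(o₁,o₂),…,oₙ), into a stride-4 map F.
Two heads predict a sigmoid center heatmap F_ct and a regression map F_reg
holding N vertex offsets per cell, so one lookup at a center yields a whole
initial contour. Contour self-attention (CSA) blocks then refine it: each
vertex's bilinear feature sample from a refined map F′ is concatenated with
its box-normalized coordinates (the contour positional embedding
x′ = (x − x_min)/(x_max − x_min)), and multi-head self-attention

MHSA(P) = P ⊕ (ReLU(P ⊕ Attention(P)) W_z1) W_z2

predicts per-vertex offsets (Δxᵢ, Δyᵢ). Training minimizes

L = L_focal + 0.5·L_OT^init + 0.5·L_OT^CSA1 + L_OT^CSA2,

where L_focal is the penalty-reduced focal loss on the heatmap, and each
contour stage is supervised as a *point-set distribution*: predicted and
ground-truth vertices become uniform discrete measures α = Σ aᵢ δ_ψᵢ,
β = Σ bⱼ δ_φⱼ (aᵢ = bⱼ = 1/N) and the loss is the debiased Sinkhorn
divergence

L_OT = OT_ε(α, β) − ½·OT_ε(α, α) − ½·OT_ε(β, β),

solved by log-domain symmetric iterations with ε annealed geometrically
(target ε = 0.05, ratio q = 0.5 on unit-box coordinates) and differentiated
analytically through the converged dual potentials. A Kuhn-Munkres
"HardAssign" baseline (minimum-cost one-to-one matching + smooth-L1) is
included for the supervision ablation.

**LWEN.** Contour coordinates are normalized against the image,
(x − W)/W and (y − H)/H, and against their own bounding box, giving an
N × 4 sequence; a linear projection to d_hide = 512 channels, one MHSA
block, mean pooling over the N positions, and a 512 → 128 → 1 head produce
the weight. Mean-pooled attention makes the prediction invariant to vertex
order, so ordered or unordered contour extractors feed it equally well. The
default network has 3.2 M trainable parameters; Wide (d_hide = 1024) and
Deep (6 MHSA layers) variants are one call away.

**Supporting components.** 64-bit perceptual-hash (DCT) frame
deduplication with Hamming threshold τ = 15; greedy multi-start TSP
ordering of unordered contour points; polygon rasterization and COCO-style
mask AP; a synthetic top-view scene generator whose animal weights are a
deterministic function of *world-space* (pre-projection) dorsal area plus
Gaussian noise, with a position-dependent apparent-size model — so
recovering weight from an image contour requires exactly the positional
normalization LWEN performs.

## Worked example

```r
library(contourweight)
set.seed(1)

# an elliptical ground-truth contour and a noisy prediction, as point sets
th    <- seq(0, 2*pi, length.out = 33)[-33]
truth <- cbind(10 + 6*cos(th), 10 + 4*sin(th))
pred  <- truth + matrix(rnorm(64, sd = 0.4), ncol = 2)

debiased_divergence(discrete_measure(pred), discrete_measure(truth))
#> [1] 0.4200714     # kg-free cost units (pixels here); 0 iff same measure

km_hard_assign(pred, truth)$loss
#> [1] 0.0586795     # HardAssign baseline: smooth-L1 over matched pairs

order_points_tsp(pred[sample(32), ])$length
#> [1] 35.43193      # shortest-found closed tour through the shuffled points

count_parameters(lwen_build(lwen_config()))$label
#> [1] "3.2M"        # default liveweight network size

sum(compute_phash(array(0.5, c(96, 96, 3))))
#> [1] 1             # constant frame: only the DC bit is set
```

The end-to-end desk-scale benchmark (synthetic 96 × 96 scenes, CPU-sized
networks) is run by `run_end_to_end(run_config("desk"))` and the
supervision × refinement ablation by `run_ablation()`; the methods
vignette (`vignettes/contourweight-methods.Rmd`) documents the study
conditions and what the synthetic benchmark does and does not show. On
this benchmark the OT-supervised contour network reaches mask AP50 of 1.0
on held-out scenes, and the liveweight network recovers geometry-linked
weights with held-out R² ≈ 0.99 and MAPE ≈ 3 % (computed by
`tests/testthat/test-acceptance.R`).

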