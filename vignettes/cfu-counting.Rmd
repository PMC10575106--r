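---
title: "Hybrid CFU counting: model, losses, localization and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid CFU counting: model, losses, localization and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfuhybrid)
```

## The problem

Counting colony-forming units (CFUs) on agar plates is a routine but
error-prone task in microbiology and food safety. Segmentation networks
such as U-Nets locate colonies pixel by pixel and a connected-component
pass turns the mask into a count, but two systematic failure modes
remain:

* **Pixel-level artifacts.** Per-pixel targets reward locally plausible
  but globally wrong activations: stray specks, ragged contours, and
  holes inside colonies each distort the region count.
* **Bezel reflections.** The rim of a glass Petri dish mirrors colonies
  growing near the water's edge. A segmenter faithfully reports these
  mirror images, so every reflected colony is counted twice.

`cfuhybrid` packages three mitigations that work together: an auxiliary
training signal that tells the encoder *where* colonies are, geometric
localization of the dish and its reflection-prone bezel, and a counting
rule that discounts bezel detections.

## The multi-loss segmentation objective

The network is a standard encoder–decoder with `levels` resolutions.
For an input of side $s$ the bottleneck grid has side $m = s / 2^{L-1}$
(so $s = 1024, L = 5$ gives $m = 64$, and the desk-scale default
$s = 256$ gives $m = 16$). Besides the usual output map
$X^{\mathrm{out}}$, the model exposes $X^{\mathrm{mid}}$: the bottleneck
feature maps averaged across channels into a single nonnegative
$m \times m$ map.

Two targets are built from annotations:

* $Y^{\mathrm{out}}$: for each colony a filled disc of radius one tenth
  of the smaller bounding-box side (minimum 1 px) around the centroid —
  a crisp binary map rather than a blurred density target
  (`build_yout()`).
* $Y^{\mathrm{mid}}$: the binary $m \times m$ indicator of colony
  centroids under floor binning; several centroids in one cell leave the
  cell at 1 (`build_ymid()`).

The alignment term couples the two grids:

$$
L_{\mathrm{mid}}(X^{\mathrm{mid}}, Y^{\mathrm{mid}}) \;=\;
-\frac{\lVert X^{\mathrm{mid}} \cdot Y^{\mathrm{mid}} \rVert_{1,1}}
      {\lVert X^{\mathrm{mid}} \rVert_F \,
       \lVert Y^{\mathrm{mid}} \rVert_F},
$$

an inner product normalized by Frobenius norms. For nonnegative
$X^{\mathrm{mid}}$ it lies in $[-1, 0]$ by Cauchy–Schwarz, reaching $-1$
exactly when the feature map is proportional to the centroid indicator
and $0$ when their supports are disjoint. It is scale invariant in each
argument, so it constrains *where* the bottleneck activates, not how
strongly. The total training objective adds the usual output-layer
losses with no weighting coefficients; the default is

$$
L \;=\; L_{\mathrm{Tversky}} + L_{\mathrm{CE}} + L_{\mathrm{mid}},
$$

with Tversky weights $\alpha = \beta = 0.5$, which reduces the Tversky
index to a smoothed Dice coefficient (`loss_config()`).

Numerical notes, in the package's own conventions:

* The printed cross-entropy form is a sum of entry-wise norms; its sign
  convention would make the loss negative and reward wrong predictions,
  so `loss_ce()` implements the standard nonnegative cross-entropy with
  probabilities clipped to $[10^{-7}, 1]$. For *training* the package
  defaults to the per-pixel mean so the term is $O(1)$ like the overlap
  terms; the summed form remains available (`ce_reduction`).
* Two Dice denominators are implemented: the product-of-norms form
  (`"as_printed"`) and the conventional sum form (`"standard"`), with
  $\epsilon = 10^{-5}$ guarding both. Training defaults to the Tversky
  term instead, which sidesteps the ambiguity.
* $X^{\mathrm{mid}}$ must be nonnegative for the $[-1, 0]$ bound; the
  channel average passes through an elementwise absolute value by
  default (ReLU/sigmoid are available). With post-ReLU bottleneck
  features the transform is a no-op; it exists so the bound holds for
  any architecture tap.
* If either bottleneck map is identically zero, $L_{\mathrm{mid}}$ is
  defined as 0 with a warning: an empty plate provides no alignment
  signal and no gradient.

## Network family

The spatial layout (input side, number of levels, bottleneck grid) is
the model's contract; the block internals are deliberately small so a
desk-scale CPU run is practical. One 3×3 convolution + ReLU per encoder
level, strided 3×3 convolutions between levels, and decoder stages that
fuse the upsampled coarse path with the encoder skip through a 3×3
convolution (a 1×1 fusion was tried first and plateaued at 75–85% blob
recall after ten epochs; the 3×3 decoder reaches ~97%). Channel growth
doubles per level but is capped at four times `base_channels` to bound
the bottleneck width. The `"residual"`
variant adds identity skips around the equal-width encoder convolutions.
The segmentation head's bias is initialized at the class-prior
log-odds (foreground prior 2%), so an untrained model predicts the
background prior rather than noise; without it, short training runs can
stall for most of their budget in an all-background plateau before the
overlap term takes hold. Forward and backward passes are plain BLAS
matrix products (a 3×3 convolution is nine shifted GEMMs); gradients
were verified against finite differences to relative error below
$10^{-6}$ for both variants.

## Dish localization

`localize_dish()` implements the geometric half of the method:

1. **Blur.** Convolution with a unit-sum discretized 2-D Gaussian
   ($\sigma = 2$ px by default), reflective boundary handling.
2. **Edges.** A Canny detector: Sobel gradients, non-maximum suppression
   along the quantized gradient direction, hysteresis at the 70th/90th
   percentiles of positive gradient magnitude.
3. **Circle Hough transform.** Edge pixels vote in a 3-D accumulator
   $A(x_0, y_0, r)$ for the circle parameters of
   $(x - x_0)^2 + (y - y_0)^2 = r^2$. Both the textbook full-cone
   voting and a gradient-directed variant (each edge pixel votes only
   along its gradient line, two candidates per radius) are implemented.
   The cascade uses gradient voting by default: it is exact for the
   strong circular edges it targets and orders of magnitude cheaper,
   which matters in interpreted R; the full-cone transform is kept as
   the reference implementation and is the one validated against an
   exhaustive brute-force accumulator in the test suite.
4. **C1/C2/C3 cascade.** C1, the outer dish edge, is the best-supported
   accumulator peak with radius in (0.43, 0.52)·min(H, W). Its center
   and radius are then refined by an algebraic least-squares circle fit
   (Kasa fit) on edge pixels in a narrow annular window, which brings
   the parameter error well under a pixel. Because the glass (C2) and
   water (C3) edges are concentric with C1, their radii are read off
   the 1-px histogram of edge-pixel distances to the C1 center: peaks
   in (0.70, 0.94)·C1.r at least 8.5 px apart (a physical glass rim
   line produces two close side-edges that must collapse to one
   circle), taken outer to inner, give C2 then C3, each refined by the
   same annular fit. This radius-ordered reading follows the
   outer-to-inner cascade directly; selecting inner circles by raw vote
   count instead turns out to misassign C3 to the glass edge, whose
   vote peak is usually stronger than the water edge's.
5. **Bezel mask.** The annulus between C3 and C1 (distances measured
   from the C1 center). If C1 or C3 cannot be established the result
   carries `found = FALSE` and an empty mask; C2 is informative only.

All thresholds above are configuration parameters
(`localize_params()`); none are prescribed by the method itself, and the
defaults were chosen so the synthetic-recovery property suite passes
with a margin.

## The hybrid counting rule

Given a predicted mask, `postprocess_mask()` replaces each region by its
filled convex hull (iterated to a fixed point, so the operation is
idempotent even when hulls merge) and fills enclosed holes. With a
successful localization, each region is assigned atomically to the dish
interior, the bezel, or off-dish by majority pixel membership (ties go
to the interior; off-dish regions are discarded), and

$$
N \;=\; \mathrm{count}(X^{\mathrm{inner}}) +
        \tfrac{1}{2}\,\mathrm{count}(X^{\mathrm{bezel}}),
$$

since a reflected colony contributes two bezel regions. Without a
localization the naive count is returned (`used_fallback = TRUE`). The
atomic assignment prevents a region straddling the water edge from
splitting into two counted fragments; the literal pixelwise masking is
available via `assignment = "pixelwise"` for comparison. $N$ can be
fractional; evaluation consumes it unrounded. The ablation modes —
naive, uniform (bezel regions at full weight), hybrid — are computed on
identical inputs by `ablation_count()` / `ablation_table()`.

## Training protocol

Per-channel z-score normalization uses training-split statistics only
(`zscore_normalize()`); splits are either 5-fold cross-validation or a
random 72/18/10 train/validation/test split, deterministic in the seed
(`make_splits()`). Optimization is Adam at an initial learning rate of
$10^{-3}$ with time-based decay $lr_t = lr_0 / (1 + d\,t)$; the decay
coefficient is not prescribed, so the package defaults to
$d = 1/\mathrm{epochs}$, halving the rate by the final epoch. After
each epoch the mean absolute count error of thresholded predictions on
the validation set is computed with naive region counting (localization
is a test-time post-process), and the checkpoint with minimal
validation MAE is retained, earlier epoch winning ties. Counts are
evaluated with

$$
\mathrm{MAE} = \tfrac{1}{N}\textstyle\sum_i |n_i - \tilde n_i|,
\qquad
\mathrm{sMAPE} = \tfrac{100}{N}\textstyle\sum_i
\frac{|n_i - \tilde n_i|}{|n_i + \tilde n_i|},
$$

MAE in colony units (the percent factor that appears alongside its
printed form is dropped — reported values are in counts), sMAPE in
percent with $0/0$ pairs contributing 0. `stratified_report()`
additionally restricts to plates with fewer than 100 true colonies,
where relative mistakes matter most.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders: a bright dish on a dark background (dish
edge at 0.45·min(H, W), interior agar zone at 0.58 inside the water
edge at 0.78 of the dish radius, a uniform bezel zone at 0.45 between
the water and dish edges, and the glass edge at 0.88 of the dish
radius drawn as a thin dark rim line; centers jittered within ~1 px);
quasi-circular anti-aliased colonies with radial intensity falloff,
radii 1.0–2.2% of the frame (realistic for colonies on a standard
dish), peak intensities 0.70–0.95; additive Gaussian noise (sd 0.02)
and a slight amber channel cast. About a quarter of the colonies grow
in the bezel strip between the water and glass edges — the agar
extends past the water line — and each such colony is mirrored across
the glass circle with probability 0.8 at full mirror strength, so both
members of the pair lie in the bezel annulus and a faithful segmenter
sees the colony twice. That is the double-counting failure mode the
hybrid rule corrects: with reflections present on a perfect mask,
halving the bezel count recovers the exact colony count. Non-overlap
is enforced by rejection sampling so the count/component identity is
exact, and every scene carries its full ground truth (circles,
per-colony geometry, colony-only and colony+reflection masks).

Training targets default to *annotation-style* maps
(`make_training_set(targets = "annotated")`): the segmentation target
is the visible mask and the validation counts are the annotated
counts, reflections included, because an annotation pipeline cannot
tell a mirror image from a colony. This choice is load-bearing. The
generator also knows the privileged colony-only truth
(`targets = "colony_only"`), and training on it teaches the network to
*suppress* reflections — the synthetic world is clean enough that ten
epochs suffice to learn the give-away geometry — which lands the method
in the regime where naive counting is already unbiased and bezel
halving can only hurt (the original study observed exactly this
inversion on its cleaner public dataset). With annotated targets the
segmenter reproduces the reflection double counting, and the hybrid
rule earns its keep.

The generator does **not** emulate agar texture, condensation, colony
morphology diversity, overlapping growth, or uneven illumination.
Passing tests on these scenes demonstrates the machinery end to end,
not real-plate accuracy; the full-scale numbers of the original study
are out of desk-scale reach by design.

## Desk-scale study conditions

The test suite and the acceptance script run one fixed experiment:
50 scenes at 256×256 (radius and geometry scaled proportionally), a
5-level plain U-Net with 8 base channels (16×16 bottleneck), the
multi-loss objective, 10 epochs, batch 4, random 72/18/10 split. On one
CPU this trains in a few minutes. Under these conditions the untrained
model's validation MAE (tens of counts with random weights) drops
to low single digits, the alignment term stays within $[-1, 0]$ every
epoch, and on 20 held-out reflective scenes the hybrid count MAE
beats the naive MAE (roughly halving it in our runs). Dish
localization recovers C1/C2/C3 radii to well under 1 px at both 512 and
256 px.

## Known limitations

* Counting assumes non-overlapping colonies; merged colonies count as
  one region (no watershed splitting).
* The dish is assumed circular and roughly frame-filling; elliptical
  projections and multi-dish images are out of scope.
* The localization pairs one reflection per colony implicitly through
  halving; no per-colony reflection matching is attempted.
* The pure-R network is deliberately small; it is a faithful testbed
  for the objective and counting rule, not a production segmenter.
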