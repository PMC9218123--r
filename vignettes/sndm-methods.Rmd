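---
title: "Counting colonies with self-normalized density maps: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting colonies with self-normalized density maps: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sndm)
```

## The counting problem and the density-map model

Counting microbial colonies on Petri dishes is a routine microbiology task:
the count decides whether a sample is contaminated. `sndm` implements the
*density-map* (DM) approach to automated counting. A convolutional
encoder--decoder maps an RGB dish image $\mathbf{x}$ to a non-negative map
$\mathbf{y} = \mathscr{M}(\mathbf{x})$ whose pixel sum equals the number of
objects; counting reduces to summing the predicted map. Ground-truth maps
are built from bounding-box annotations: each box center is stamped onto an
empty map as a single unit of mass and blurred with a Gaussian kernel, so the
map integrates to the colony count by construction.

The network is a two-level nested U: a top-level U-shaped encoder--decoder
whose blocks are themselves small U-shaped residual units (RSU). Every
decoder block and the bottleneck emit a *side* logit map $S_1..S_K$,
upsampled to output resolution; a $1\times1$ convolution over their
concatenation yields the fused logit $S_0$, and $P_i = \sigma(S_i)$ are the
probability maps. Training uses *deep supervision*: the loss is the sum over
all maps (fused and side) of the pixel-summed binary cross entropy

$$\mathscr{L}(P, P^G) = -\sum_{i,j} \left[ P^G_{ij} \ln P_{ij} +
  (1 - P^G_{ij}) \ln (1 - P_{ij}) \right].$$

We keep the *sum* (not the mean) over pixels: per-map losses scale with map
area, and the published optimizer constants were tuned against this
convention.

## Self-normalization

A plain DM model localizes colonies well but can misestimate the overall
normalization of its map — underestimating crowded dishes, overestimating
nearly empty ones. Because each output pixel is a sigmoid, the map cannot be
rescaled after the fact; instead the *self-normalized density map* (SNDM)
rescales the logits: $P_i = \sigma(\beta S_i)$, with a per-image scalar
$\beta$ predicted by a bypass head attached to the deepest encoder block
(global average pooling, two fully connected layers, and the activation
$\beta = \lambda\,\sigma(z)$ with $\lambda = 1.5$, bounding $\beta$ to
$(0, 1.5)$; a ReLU variant is available). Near zero the sigmoid is
approximately linear, $\sigma(x) = \tfrac12 + \tfrac{x}{4} + O(x^3)$, so
rescaling the logits rescales the map's departure from $\tfrac12$ almost
linearly — that is the handle the head uses to fix the normalization. Since
a well-calibrated model needs no correction, the loss carries the penalty
$\tfrac12(1-\beta)^2$ per image, expressing the prior $\beta \approx 1$.

Design points the architecture leaves open, and what this package does:

* $\beta$ multiplies **all** logit maps including the fused $S_0$ (the
  rescaling is defined for "each $S_i$"; including the fused map keeps the
  final output consistent with the supervised side maps).
* The bypass head is deliberately tiny — GAP, FC(hidden 32), FC(1) — to
  limit its parameter count.
* Its final bias is initialized so that $\beta = 1$ exactly at the start of
  training (no correction until the data demands one).
* The head warms up frozen: for the first `beta_freeze_epochs` (default 5)
  of training it stays at its $\beta = 1$ initialization, then trains at
  full rate. All of its parameters push a single scalar through a
  saturating activation; trained from the first step — while the logit maps
  are still badly scaled and the cross entropy briefly favours a large
  global rescaling — $\beta$ slams into saturation, where gradients vanish
  and recovery costs many epochs. Merely damping the head's learning rate
  avoids the slam but also suppresses the *per-image* dependence of
  $\beta$, which is the mechanism's entire point; freezing first and then
  releasing at full rate preserves both.
* Upsampling is bilinear; fusion weights start at the side-map average.
* Spatial (channelwise) dropout, default rate 0.1, sits after each block's
  inner bottleneck and inner decoder output, identically in DM and SNDM
  mode, so Monte Carlo dropout is available for both.

## Density targets: conservation as the contract

`render_density_target()` gives each colony a truncated Gaussian kernel
(default truncation $4\sigma$) renormalized to unit mass *per colony* after
truncation and edge clipping. This guarantees the pixel sum equals the count
exactly (to float tolerance) for any geometry, including near-edge colonies,
and preserves superposition (rendering is additive in the centers). The blur
width is adaptive by default, $\sigma = 0.25 \times$ the mean box side at
target resolution, floored at 0.4 px; the floor keeps an isolated kernel's
peak $1/(2\pi\sigma^2) \le 1$, so targets are valid per-pixel probabilities
for the cross entropy. Overlapping colonies can still push a pixel above 1;
the loss consumes a clipped view (`loss_view()`, clipping to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, with a warning when
clipping truncates) while counts are always read off the unclipped map.
How the original training handled target pixels above 1 is not documented;
the clipped loss view is this package's choice.

## Uncertainty quantification

Two standard frameworks, both aggregating with the *population* divisor
($B$, not $B-1$):

* **Bootstrap (pairs sampling).** $B$ training subsets are drawn with
  replacement, each of exactly $b = \mathrm{round}(0.63\,N)$ draws
  (defaults $B = 20$, fraction 0.63); each member trains from a fresh
  initialization and is selected on the shared validation set. The ensemble
  mean is the prediction; the root of the ensemble variance is the
  $1\sigma$ uncertainty. For members that equal truth plus i.i.d. noise of
  variance $v$, the ensemble-mean squared error is $\approx v/B$.
* **MC dropout.** $r = 20$ stochastic forward passes with dropout kept
  active, aggregated identically with divisor $r$.

Scalar count uncertainty is always computed from per-member *counts* (each
the pixel sum of that member's fused map), never by aggregating the
per-pixel sigma map — pixels are strongly correlated, and summing their
variances would be wrong. Per-pixel mean and sigma maps are reported
separately with the same formulas applied pixelwise.

## Metrics and diagnostics

`count_mae()` and `count_smape()` implement
$\mathrm{MAE} = \frac1N \sum |n_i - \tilde n_i|$ and
$\mathrm{sMAPE} = \frac{100}{N} \sum |n_i - \tilde n_i| / |n_i + \tilde n_i|$,
with the $0/0$ term (an empty dish predicted empty) defined as 0 — empty
dishes are a deliberate part of the benchmark and must not crash or inflate
the metric. Predicted counts stay unrounded for metrics. Reports stratify at
50 colonies by default (less/more crowded dishes), and diagnostics bin the
uncertainty by mean colony size, dish coverage, or true count, and fit
ordinary least-squares lines of $\beta$ against coverage within
colony-size groups (degenerate groups are flagged, not dropped).
"Mean colony size" is defined here as the mean equivalent diameter
$\sqrt{wh}$ of the boxes — robust to aspect ratio.

## The synthetic dish generator

Real annotated dish collections are large, request-only and
GPU-scale; the package instead generates annotated scenes that reproduce the
statistical shape of such data at desk scale: a circular dish on a dark
background with a bright rim; three illumination modes (uniform, linear
gradient, vignette); colonies as soft-edged disks with log-normal radii
(median 3 px at 96 px images, spread 0.3 on the log scale), allowed to
overlap and to touch the dish edge; additive Gaussian pixel noise
($\sigma = 0.01$); and a count mixture on $0..100$ with 85% of mass below
50 colonies (truncated negative binomial bulk, uniform tail), matching the
"about 85% of samples have fewer than 50 colonies" property of the emulated
data, empty dishes included. Bounding boxes use 0-based, half-open pixel
coordinates; the colony center is the box midpoint, which is exactly the
convention the density targets consume.

What the generator does **not** emulate: species-specific morphology and
texture, specular reflections, condensation, agar artifacts, annotation
noise, and the sheer image scale (thousands of pixels per side). Passing
tests therefore demonstrate that the machinery — targets, network,
normalization, uncertainty, metrics — behaves as specified on data with the
right statistical shape; they do not certify accuracy on real photographs.

## Desk-scale study conditions and numerical choices

All shipped experiments run on one CPU. The miniature network preset uses 3
encoder stages (5 blocks, 3 side outputs), base width 4--6 channels, inner-U
depth 1, and 96 px inputs with the density target on the same grid; the
full-scale layout (6 stages, 11 blocks, 6 side outputs, inputs resized to
around 1000 px) is constructible and structurally tested, but training it
reproduces a multi-day GPU workload and is out of scope. The end-to-end
comparison trains on 300 scenes (210/30/60 split) with counts on $0..60$,
85% below 30, for 20 epochs, and strati­fies at 30 colonies — the
proportional analog of the 50-colony boundary on the full $0..100$ range.

Optimization is Adam with the published constants (learning rate $10^{-4}$,
weight decay $5\cdot10^{-4}$, batch size 2) as defaults. Desk-scale runs use
learning rate $10^{-3}$: the published rate was tuned against megapixel
maps under the pixel-sum loss convention, and at $96^2$ maps (two orders of
magnitude fewer pixels) the same rate barely moves the parameters within a
short epoch budget. Early stopping monitors the validation count-MAE
(patience 10 by default) and restores the best checkpoint; the penalty
weight is exposed but defaults to 1, matching the published loss, which has
no extra hyperparameter.

Numerical details worth knowing: BCE computations add $10^{-12}$ inside the
logs for safety; the network rejects input sizes not divisible by
$2^{\text{stage}+\text{depth}}$ at every stage (pooling is exact 2x);
max-pool backward routes to the argmax; bilinear upsampling uses the
half-pixel-center convention and its exact adjoint in the backward pass.
All randomness (initialization, shuffling, dropout, scene synthesis) flows
through R's RNG, so a seed reproduces scenes, training histories and
ensembles bit-exactly on a fixed platform; every ensemble member derives
its own initialization and shuffling seed from one master seed.

## Known limitations

* The backbone is a miniature analog; absolute error rates on the synthetic
  benchmark do not transfer to real high-resolution dish photographs.
* $\beta$ is bounded by the default activation to $(0, 1.5)$; a dish whose
  correct correction exceeds the bound saturates the head (the ReLU variant
  removes the bound at the cost of an unconstrained scale).
* The $\beta$ head can still saturate when the required correction exceeds
  what the penalty tolerates; the damped head learning rate mitigates but
  does not eliminate this.
* Dishes mixing very different colony sizes remain the hard case: the
  correct normalization depends on colony size and coverage jointly, and a
  single scalar $\beta$ per image cannot fix both strata at once.
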