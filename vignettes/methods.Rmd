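---
title: "Dynamic convolution decomposition and triplet attention in an Attention U-Net: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTA-UNet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtaunet)
```

## The segmentation problem

Lesion segmentation across modalities (stroke MRI, pneumonia CT, dermoscopy)
shares two difficulties: lesions vary enormously in size, shape and location,
and their boundaries are blurred. `dtaunet` implements a family of
encoder–decoder networks built to address both: an Attention U-Net backbone
whose convolutions can be made *input-dependent* through dynamic convolution
decomposition (DCD), with skip connections refined by triplet attention (TA)
in combination with the attention gates (AG). The fully equipped network is
DTA-UNet.

## Dynamic convolution decomposition

A conventional convolution applies one kernel to every input. Dynamic
convolutions instead mix several kernels with input-dependent attention
weights; the decomposition view replaces that mixture by

$$W(x) \;=\; \Lambda(x)\, W_0 \;+\; P\, \Phi(x)\, R^\top ,$$

where $W_0$ is a static mean kernel, $\Lambda(x)$ is a diagonal matrix of
per-output-channel gates, and the second term is a low-rank dynamic residual
in kernel-element space: $R \in \mathbb{R}^{k^2 \times L}$ compresses the
$k^2$ kernel elements into a latent space of dimension
$L = \lfloor k^2/2 \rfloor$ (so $L = 4$ for $k = 3$), $\Phi(x) \in
\mathbb{R}^{L \times L}$ fuses the latent components per input, and
$P \in \mathbb{R}^{C_\mathrm{out} \times L}$ raises the result back to output
channels.

Two aspects of this formula leave room that an implementation must close,
and our choices are:

* **Input-channel axis.** The decomposition treats the kernel as a
  $C \times k^2$ matrix, which does not span the input-channel axis of a
  general convolution. We keep $W_0$ as a full
  $C_\mathrm{out} \times C_\mathrm{in} \times k \times k$ kernel, let
  $\Lambda(x)$ scale whole output-channel slices, and broadcast the residual
  $P\Phi(x)R^\top$ (a $C_\mathrm{out}\times k^2$ matrix) uniformly over input
  channels after dividing by $C_\mathrm{in}$. The division keeps the residual's
  magnitude and its parameter cost independent of the layer width on the
  input side.
* **The attention generator.** $\Lambda(x)$ and $\Phi(x)$ are "generated by
  attention"; the generator itself is unconstrained by the formula. We use a
  squeeze-and-excitation form: global average pooling to a $C_\mathrm{in}$
  descriptor, two bias-free rectified linear maps of width
  $h = \max(8, \lfloor \max(C_\mathrm{in}, C_\mathrm{out})/r \rfloor)$, and
  two bias-free heads of sizes $C_\mathrm{out}$ (for $\Lambda$) and $L^2$
  (for $\Phi$). Bias-free excitation layers follow the squeeze-and-excitation
  lineage; the minimum bottleneck width follows the mobile-network
  `make_divisible` convention. The reduction ratio $r$ and this structure
  were fixed by requiring that the *total* trainable-parameter count of the
  assembled networks reproduce the published ablation table of this
  architecture family at its printed 4-decimal precision; $r = 11$ is the
  unique value in this family that does. The per-side (encoder-only /
  decoder-only) deltas of that table cannot be matched simultaneously with
  the totals by any single generator structure we searched — an exhaustive
  scan over descriptor sources, hidden-width rules, bias placements and
  reduction ratios ruled it out — so the package matches the totals exactly
  and the per-side counts approximately (they differ in the fourth decimal
  of the millions figure, with errors of opposite sign that cancel in the
  sum).
* **Gate squashing.** $\lambda = 1 + \tanh(\cdot)$, bounded in $(0,2)$ and
  equal to 1 at zero pre-activation. With the heads zero-initialised, a fresh
  DCD layer is therefore *exactly* the static convolution $W_0$ — a warm
  start that also gives the test suite a sharp fixed point to verify.
* **The replaced convolution's bias is dropped** (a bias is redundant before
  batch normalization); the conventional units keep theirs, since the
  published parameter counts of the baseline require it.

The per-sample kernel is never materialized in the fast path: with the
im2col matrix $C$ of a sample,
$C\,W(x) = \mathrm{colscale}_\lambda(C\,W_0) + \tilde{C}\,(P\Phi R^\top)^\top/C_\mathrm{in}$,
where $\tilde{C}$ sums $C$ over input channels. A contract test asserts that
this batched route and the explicit per-sample loop agree to $10^{-6}$, and
both are checked against a plain nested-loop convolution oracle.

## Triplet attention

TA computes three near-parameter-free gates, one per pair of tensor axes:
each branch exposes a plane — (H,W) pooling channels, (H,C) pooling width,
(C,W) pooling height — compresses the pooled axis to two channels with
Z-Pool,

$$\mathrm{ZPool}(f) = [\mathrm{MaxPool}_{0d}(f),\ \mathrm{AvgPool}_{0d}(f)],$$

convolves the two-channel plane with a single $7\times 7$ kernel (padding 3),
normalizes, squashes with a sigmoid and multiplies the input elementwise;
the three gated tensors are averaged with equal weight $1/3$. Each branch
owns $2k_{ta}^2$ kernel weights plus one normalization scale and shift:
$3(2\cdot 49 + 2) = 300$ trainable scalars per module regardless of channel
width. The 90° rotations of the original formulation are realized as index
arithmetic inside the pooling and gating kernels; an exact equality test ties
every branch back to the rotate–ZPool–restore formulation. The literature is
not fully explicit about which two branches share structure; the plane
assignment is isolated in one table (`ta_modes`) so it can be corrected in
one place.

## Attention gates and the backbone

The additive attention gate maps the encoder skip feature and the decoder
gating signal through $1\times1$ convolutions (with bias and normalization)
to an intermediate width $C_\mathrm{int} = C_\mathrm{skip}/2$, adds,
rectifies, reduces to a single channel, and squashes:
$\alpha = \sigma(\psi(\mathrm{ReLU}(W_x s + W_g g)))$, returning
$s \odot \alpha$.

The backbone has five scales with widths 64–1024 (doubling), double
convolution units per scale (conv 3×3 + batch norm + ReLU), 2×2 max pooling,
and a decoder stage of: bilinear 2× upsampling, a 3×3 conv unit halving
channels, the attention gate (gated by that upsampled, convolved feature),
concatenation (skip first), a double conv unit, and finally a 1×1 head with
sigmoid. Decisions worth recording:

* **TA placement**: after the double convolution of each encoder scale
  (including the bottleneck) and after the double convolution of each decoder
  stage — 5 + 4 = 9 insertions. This is the only placement consistent with
  the published per-side TA parameter deltas (+0.0015 M encoder,
  +0.0012 M decoder at 300 scalars per module).
* **DCD placement**: the dual convolutions of encoder and decoder. The
  decoder's up-sampling convolution stays conventional — the decoder is
  described in this family as carrying *dual* dynamic convolutions, and the
  parameter budget confirms it.
* **Plain U-Net comparison model**: same encoder, 2×2 transposed-convolution
  upsampling (with bias), no gates, no TA. Bilinear (parameter-free)
  upsampling in the attention family and transposed convolutions in the plain
  U-Net are the only combination that reproduces both published totals
  (34.8786 M and 31.0435 M).
* **Input channels**: 3 everywhere; grayscale images are replicated at load
  time, so one architecture (and one parameter count) serves MRI, CT and
  dermoscopy alike.
* **Initialization**: fan-in-scaled normal draws for kernels, scale 1 /
  shift 0 for normalizations, zero for the DCD heads, all under one seed;
  `make_variant(spec, cfg, seed)` is deterministic.

## Training

`train()` implements the standard loop for this family: seeded shuffling,
minibatches of 12, mean pixelwise binary cross-entropy

$$L = -\tfrac{1}{N}\textstyle\sum_i \big(y_i \log p_i + (1-y_i)\log(1-p_i)\big),$$

and Adam with learning rate $10^{-3}$, $\beta = (0.9, 0.999)$,
$\epsilon = 10^{-8}$ — the last three are unstated in the protocol this
follows and are the optimizer's standard defaults. No learning-rate schedule,
no augmentation, no early stopping. The loss gradient is taken with respect
to the head logits ($(p - y)/N$), which is the exact derivative and avoids
the instability of differentiating through the clipped probability; the
clipping ($\epsilon = 10^{-7}$) guards only the reported loss value. Best and
final checkpoints are kept because reporting conventions differ on which one
a test metric should use; evaluation accepts either.

## Metrics

IoU, Dice and precision come from pixel confusion counts; the Hausdorff
distance is the symmetric max–min Euclidean distance between the *full*
foreground point sets (no boundary extraction, no 95th-percentile variant),
in pixel units. Conventions the definitions leave open, fixed in one place:
when both masks are empty IoU, Dice and precision are 1; when the prediction
alone is empty precision is 1; the Hausdorff distance of an empty set is
undefined — recorded as `NA` with a warning and skipped in aggregation.
Test-set aggregation is the unweighted mean of per-image metrics (matching
per-patient presentation), not a pooled-pixel figure; the binarization
threshold defaults to 0.5, the natural operating point of a sigmoid trained
with cross-entropy.

## Synthetic phantoms

The generator emulates the two shared properties of the target datasets:
widely varying lesion size/shape/location, and blurred boundaries. Each
phantom is a textured background (Gaussian-smoothed noise plus pixel noise)
with 1–3 lesions: rotated ellipses with an overall size drawn log-uniformly
from the radius range (4–60 px at the default 256 px canvas — log-uniform so
that small lesions are as common as large ones and areas span orders of
magnitude), an eccentricity in $e^{\pm0.4}$, and a low-order boundary
perturbation (modes 2–4, relative amplitude ≤ 0.15). The rendered lesion is
added at `contrast` (default 0.35) and Gaussian-blurred ($\sigma = 2$ px);
the mask is exactly the pre-blur support, so the label is crisp while the
image boundary is not — the property that makes boundary-sensitive metrics
informative. Everything is deterministic given the seed; datasets are written
as 8-bit PNGs with a JSON manifest and an 80/20 seeded split.

What phantoms do *not* emulate: anatomy and its spatial context, modality
physics (bias fields, partial-volume effects, speckle), annotation noise,
and inter-patient intensity variation. Passing the end-to-end checks on
phantoms therefore demonstrates that the architecture, gradients and training
loop are correctly wired and can fit segmentation structure — it does not
certify clinical segmentation quality.

## Numerical choices and problem sizes

All convolution, pooling and normalization arithmetic runs in single
precision through BLAS; parameters and optimizer state stay in double
precision. Batch-norm uses $\epsilon = 10^{-5}$ and momentum 0.1 for running
statistics (used at evaluation). Max-pool and Z-Pool ties route the gradient
to the first maximum in a fixed scan order. Oracle-equivalence tests run at
tolerances of $10^{-5}$–$10^{-6}$, reflecting single-precision accumulation.

The test suite chooses problem sizes as follows: oracle and property tests
use layers of up to 4 channels on grids up to 8×8, where nested-loop
references are exact and fast; network-level tests use a width-reduced
configuration (4–64) at 32×32; and the end-to-end overfit check trains the
complete DTA-UNet wiring — DCD and TA in both encoder and decoder, attention
gates on every skip, all five scales — at widths 16–256 on 16 phantoms of
64×64 for 200 epochs with batch 12 and Adam at $10^{-3}$, requiring training
Dice ≥ 0.95 and a strictly decreasing loss trend. The width reduction is the
package's problem-size choice for that check: capacity per parameter is
width-independent for this test's purpose (16 images are far inside the
capacity of either width), while the full 64–1024 configuration multiplies
the arithmetic by roughly 16×. Parameter-count checks always use the full
64–1024 configuration, since the published counts are specific to it.

## Known limitations

* Two published per-side ablation parameter counts (DCD in encoder only /
  decoder only) are reproduced only approximately (see above); the baseline,
  TA, combined-DCD and full-model counts are exact.
* Training is CPU-only and single-threaded; it is intended for method
  verification and small studies, not for full-scale training runs.
* Binary (single-lesion-class) segmentation only; no multi-class head.
* The Hausdorff implementation enumerates full point sets; for very large
  foregrounds it is memory-chunked but still quadratic in the worst case.
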