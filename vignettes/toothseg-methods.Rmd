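---
title: "Methods: attention-augmented U-Net segmentation of tooth CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-augmented U-Net segmentation of tooth CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Axial dental CT slices are hard to segment automatically: tooth enamel and
dentine sit directly against alveolar bone and soft tissue of similar
attenuation, so tooth/tissue boundaries are blurred and low-contrast;
gray level varies both between teeth and within a single tooth. `toothseg`
implements a semantic-segmentation pipeline built for exactly this regime:
a U-Net encoder–decoder whose channel attention is computed from
*sub-region average pooling* (SAP) rather than global average pooling, so
that coarse spatial layout still informs the channel weights, plus the
matching preprocessing, augmentation, training schedule, and evaluation
metrics. Because clinical dental CT collections are rarely shareable, the
package ships a synthetic tooth-phantom generator that reproduces the
statistical difficulties above with exact ground truth, making every stage
of the system trainable and testable end to end.

## The attention mechanism

All attention operates on `H x W x K` feature maps and produces one weight
per channel.

**Squeeze–excite baseline.** Global average pooling shrinks each channel
to its spatial mean, `z_c = (1/HW) * sum_{i,j} u_c(i,j)`. A two-layer
bottleneck with reduction ratio `C` (default 16) and a sigmoid gate gives
`s = sigmoid(W2 . relu(W1 . z))`, and channels are rescaled as
`X_c = s_c * u_c`. `W1` is `(K/C) x K`; `W2` must be `K x (K/C)` so the
excitation returns to `K` dimensions before the gate — the only shape
assignment under which the chain composes and `s` has one weight per
channel.

**Sub-region average pooling.** GAP throws away all spatial structure.
SAP instead pools over an `m x n` grid of near-equal rectangles (cell
boundaries at `floor(H*i/m)`), producing an `m x n x K` summary. For each
output channel `r`, an `m x n` kernel `phi_r` is applied across the grid
and summed over all input channels; the sigmoid of the resulting scalar is
the high-level attention weight `eps_h[r]`. With grid `(1,1)` this reduces
exactly to GAP-based attention; with grid `(H,W)` the pooling is the
identity. The kernel output is a scalar per channel, broadcast over
`H x W` during recalibration — the only reading under which the fused
weights have one value per channel.

**Channel expansion (CE).** Low-level (skip) features carry boundary
detail but have fewer channels than the decoder feature they should
modulate. The CE branch pools the skip feature over the same grid,
averages the cells per channel, expands the resulting `K_low` vector to
`K` channels with a `1 x 1` (matrix) transform, and applies a sigmoid,
giving `eps_l`. The branch internals are deliberately minimal — pooling,
one linear channel expansion, one nonlinearity — and reproduce the natural
degenerate case: identity weights and grid `(1,1)` give the sigmoid of the
per-channel means.

**Fusion and recalibration.** The fused distribution is the elementwise
sum `eps_F = eps_l + eps_h`. Each component lies strictly in `(0, 2)`: the
supremum 2 is the sum of the two sigmoid suprema and is approached but
never attained. The recalibrated map is `U_hat = U * eps_F` channel-wise,
so a channel can be amplified (weight > 1) as well as suppressed — the
reason the sum is not renormalized. The package tags weight vectors with
their range (`sigmoid` vs `fused`) and rejects double fusion, which would
silently change the range contract.

## Network architecture

The encoder halves resolution four times (3x3 conv–ReLU pairs with 2x2
max pooling), so the head feature sits at 1/16 of the input. The deepest
block is three 3x3 convolutions dilated at rate 2 — receptive-field
growth standing in for a fifth downsampling. An ASPP head runs parallel
branches (1x1 conv; 3x3 convs at the configured dilation rates, default
1/2/4; and an image-level branch that SAP-pools the head, applies a 1x1
conv, and upsamples back), concatenates them, and projects to the decoder
width. The decoder performs one or more *attended merges*: at each
configured encoder stage it upsamples the running feature to that stage's
resolution, adds the 3x3-convolved skip feature, merges with a 3x3
convolution, and recalibrates the merged feature with that merge's fused
SAP/CE attention, before restoring full resolution bilinearly ahead of a
1x1 classifier.

Open choices, decided as follows:

* **Skip merging by addition**, with the skip feature first passed through
  a 3x3 convolution to the decoder width. (Concatenation is the other
  common choice; addition keeps the decoder width independent of the
  encoder widths.)
* **Merge stages.** `net_config(decoder_merges =)` lists the encoder
  stages merged back in, coarse to fine; the default is a single merge at
  1/4 resolution. On small inputs whose structures are only a few pixels
  wide, held-out accuracy rises monotonically with the resolution of the
  final merge — boundary detail dominates the error — so the reduced
  desk-scale configuration merges at 1/2 and then full resolution
  (`c(2,1)`); the full ladder `c(3,2,1)` has more capacity but underfits
  short training budgets.
* **Attention attachment.** At every merge, `eps_h` is computed from the
  upsampled high-level feature entering that merge, `eps_l` from the skip
  feature feeding it; the fused weights recalibrate the merged feature.
* **Stage widths** double per stage from `base_width`; the exact widths of
  the original design are not recoverable, so they are configuration, not
  claim.
* **Upsampling** is bilinear everywhere, implemented as left/right
  multiplication by 1-D interpolation matrices; its backward pass is the
  exact transpose, which the finite-difference tests exploit.
* **Initialization**: He-normal for convolution kernels, zeros for biases.

The network is implemented directly in R as explicit forward/backward
passes over `H x W x C` arrays. Convolution is evaluated as nine (per-tap)
BLAS matrix products per 3x3 kernel, which keeps the whole system in
interpreted code short enough to audit while remaining fast enough for the
desk-scale problem sizes below. Every analytic gradient is checked against
central finite differences in the test suite.

## Preprocessing and augmentation

Inputs are enhanced with histogram equalization — global (HE) or
contrast-limited adaptive (CLAHE, default 8x8 tiles, clip limit 2.0, the
usual defaults in the CLAHE literature) — then min–max normalized to
[0, 1] at size 512 x 512. HE maps each pixel through the image's own
cumulative distribution over 256 equal-width bins; a constant image is
degenerate and returned unchanged, and a constant image under
normalization maps to 0.5 by convention. CLAHE shares the same CDF
convention per tile and interpolates tile tables bilinearly, so a single
unclipped tile reduces exactly to HE.

Four augmentation operators act on image/mask pairs, always with the same
geometric transform for both (nearest-neighbor for masks so labels stay
integral):

1. **Random crop** (default window 0.9 of the side, resized back);
2. **Flip** (horizontal/vertical);
3. **Gray perturbation** — additive zero-mean Gaussian noise (default
   sigma 0.02) on the image only. Whether the original perturbation was
   additive, multiplicative, or gamma-shaped is not recoverable; additive
   is implemented and configurable.
4. **Shape perturbation** — the upper-left, upper-right, and lower-left
   corners are each displaced uniformly by at most a fraction of the image
   side (default 0.1), and the unique affine map sending the original
   corners to the displaced ones warps the whole pair. A displacement
   range equal to the full image side would destroy the content, so the
   range is read as a fraction; 10% matches common affine-augmentation
   practice.

Offline enlargement by factor `f` keeps each original and adds `f - 1`
freshly composed variants, so 400 training + 100 validation slices at
factor 3 give exactly 1500 samples. Enlargement is offline (the printed
total is a dataset size, not an iteration count), with per-variant seeds
derived deterministically from the master seed.

## Training

SGD with momentum 0.9 and weight decay 1e-4; polynomial learning-rate
decay `lr = lr0 * (1 - iter/max_iter)^power` with `lr0 = 8e-3`,
`power = 0.9`, and a budget of 800 iterations, where an iteration is one
optimizer step. The loss is pixel-wise softmax cross-entropy (the
original loss is unstated; cross-entropy is the standard choice for
U-Net-style semantic segmentation). Validation predictions are per-pixel
argmax with ties broken toward the lower class index.

## Evaluation

Both indices come from a pooled `(k+1) x (k+1)` pixel confusion matrix
with background as class 0:

* **MPA** — per-class fraction of correctly segmented pixels, averaged
  over classes: `mean_i( n_ii / sum_j n_ij )`.
* **MIoU** — per-class intersection over union, averaged:
  `mean_i( n_ii / (sum_j n_ij + sum_j n_ji - n_ii) )`.

Classes that never occur (empty row for MPA, empty union for MIoU) are
excluded from the averages rather than propagating 0/0. Pooling is over
the whole evaluation set, not per image (per-image averaging is available
via `evaluate_masks` on single pairs). Both conventions are the common
ones in semantic segmentation; neither changes the value when all classes
are present in every image.

## The phantom generator

Each synthetic slice composites 8–14 teeth — two arcs of rotated ellipses
forming a dental arch — over a uniform tissue background, then blurs and
noises the whole frame; the ground-truth mask marks the unblurred
elliptical supports. Defaults (for 512 x 512 slices): tooth gray
0.65 ± 0.08 against tissue 0.45, boundary blur sigma 1.5 px, additive
noise sigma 0.05. These were chosen once to land in the low-contrast,
blurred-boundary regime that motivates the attention mechanism while
remaining learnable; the inter-tooth gray jitter creates the between-teeth
variation, and blur plus noise create the within-tooth variation.

What the phantom does **not** emulate: beam hardening and metal-artifact
streaks, anatomical tooth cross-sections (pulp chambers, roots), 3D
partial-volume effects, and scanner-specific noise correlation. Passing
tests on phantoms therefore demonstrate that the implementation learns and
evaluates correctly under low contrast and blurred boundaries — not
clinical-grade performance on real CT.

## Desk-scale problem sizes

The test suite and examples run every stage at reduced size so the whole
system remains auditable on a single CPU:

* Structural and oracle tests use feature maps of a few hundred elements
  and networks with `base_width` 2–4.
* The learning-capability check trains the reduced configuration
  (`base_width = 8`, ASPP rates 1/2, SAP grid 2x2, decoder merges at 1/2
  and full resolution, batch 4) on 32 phantom slices at
  64 x 64 — generated with the phantom defaults, so teeth are only a few
  pixels across — for 300 iterations, and expects held-out MIoU of at
  least 0.80.
* The end-to-end determinism check runs the full generate → preprocess →
  augment → train → evaluate pipeline twice at small size and compares
  the metrics files byte for byte.

## Known limitations

* Single-image batching: gradients are averaged over the batch by looping,
  which is exact but not vectorized across samples.
* The trainer applies weight decay to all parameters, biases included
  (documented; the distinction is immaterial at these scales).
* CLAHE redistributes clipped histogram mass in one pass, so the
  effective clip is approximate for extreme limits — the standard
  single-pass behavior.
* `n_teeth` counts are drawn per slice; the generator does not model
  missing/filled teeth or implants.
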