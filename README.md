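# toothseg

Semantic segmentation of 2D dental CT slices with an attention-augmented
U-Net, implemented as a self-contained R package: network, trainer,
preprocessing/augmentation, metrics, and a synthetic tooth-phantom
generator that stands in for clinical data.

## The problem and the method

Tooth CT slices are notoriously low-contrast: enamel and dentine sit
against bone and soft tissue of similar gray level, boundaries blur, and
gray values vary between and within teeth. The package addresses this
with a U-Net encoder–decoder whose channel attention is computed from
**sub-region average pooling (SAP)** instead of global average pooling,
fused with a low-level **channel-expansion (CE)** branch:

- squeeze–excite baseline: `z_c = (1/HW) Σ_ij u_c(i,j)`,
  `s = σ(W₂ δ(W₁ z))`, `X_c = s_c · u_c` (reduction ratio C = 16);
- SAP: pool to an `m×n` grid of spatial means, apply one `m×n` kernel
  `φ_r` per channel summed over input channels, gate with a sigmoid →
  high-level weights `ε_h`;
- CE: pool the low-level skip feature, expand its channels to the
  high-level count with a 1×1 transform, gate with a sigmoid → `ε_l`;
- fusion: `ε_F = ε_l + ε_h ∈ (0,2)` per channel — weights can suppress
  *or amplify* — and recalibration `Û = U · ε_F`.

The network uses a dilated deepest block (rate 2, output stride 16), an
ASPP head with an SAP image-level branch, and a decoder that merges an
attention-recalibrated low-level skip. Training follows SGD (momentum
0.9, weight decay 1e-4) under the polynomial schedule
`lr = 8e-3 · (1 − iter/max_iter)^0.9` for 800 iterations; evaluation
reports MPA and MIoU from a pooled pixel confusion matrix. All
forward/backward passes are hand-written over plain R arrays and verified
against finite differences in the test suite.

## Worked example

```r
library(toothseg)

# one synthetic slice: low-contrast teeth, blurred boundaries
cfg <- phantom_config(image_size = 64, seed = 7)
sp  <- generate_slice(cfg)
sp
#> sample_pair: 64 x 64 | classes: 0,1 | foreground fraction: 0.0994

# preprocess, train a reduced network, evaluate held-out slices
pairs <- lapply(1:32, function(i) {
  p <- generate_slice(phantom_config(image_size = 64,
                                     seed = slice_seed(11, i)))
  p$image <- preprocess_image(p$image, "ahe")
  p
})
net <- build_network(net_config(base_width = 8, aspp_rates = c(1, 2),
                                sap_grid = c(2, 2),
                                decoder_merges = c(2, 1), init_seed = 5))
fit <- train(net, pairs[1:24],
             train_config(max_iter = 300, batch_size = 4, seed = 2))
vm <- validate(fit$net, pairs[25:32])
round(c(MPA = vm$mpa, MIoU = vm$miou), 3)
#>   MPA  MIoU
#> 0.905 0.819
```

`MPA` is the per-class pixel accuracy averaged over background and tooth;
`MIoU` the per-class intersection-over-union average, the stricter index:
0.82 here means tooth boundaries are recovered to well under a pixel on
held-out phantoms after 300 optimizer steps.

The attention blocks are usable on their own:

```r
u  <- array(rnorm(16 * 16 * 8), c(16, 16, 8))     # H x W x K feature map
p  <- sap_params(grid = c(2, 2), K = 8, K_low = 4)
eh <- sap_attention(u, p)                         # high-level weights
el <- ce_attention(array(rnorm(16 * 16 * 4), c(16, 16, 4)), p)
uf <- recalibrate(u, fuse_attention(el, eh))      # channel recalibration
range(fuse_attention(el, eh))                     # strictly inside (0, 2)
```

A command-line interface wrapping the same functions ships in
`inst/cli/toothseg.R` (verbs: `generate`, `preprocess`, `train`, `eval`,
`predict`, `summary`).

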