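# dtaunet

Encoder–decoder lesion segmentation networks for 2-D medical images, in R.
The package implements **DTA-UNet**: an Attention U-Net backbone in which
every 3×3 convolution of the encoding–decoding path can be replaced by
**dynamic convolution decomposition (DCD)** and skip connections are refined
by **triplet attention (TA)** combined with the attention gates. It is aimed
at method developers and reviewers who want a self-contained, CPU-only,
fully deterministic implementation of this architecture family — with an
ablation variant factory, an exact trainable-parameter counter, a
segmentation metric suite, a seeded synthetic lesion-phantom generator and a
reproducible training pipeline — without a GPU deep-learning stack.

## The model

A DCD layer builds a *per-sample* convolution kernel

```
W(x) = Λ(x) W₀ + P Φ(x) Rᵀ
```

from a static mean kernel `W₀`, a diagonal channel-attention matrix `Λ(x)`,
and a low-rank dynamic residual: `R` (k²×L) compresses the k² kernel
elements to a latent dimension `L = ⌊k²/2⌋` (L = 4 for k = 3), `Φ(x)` (L×L)
fuses the latent components per input, and `P` (C_out×L) raises the result
back to output channels. `Λ(x)` and `Φ(x)` come from a small
squeeze-and-excitation hyper-branch on the globally pooled input.

TA is a near-parameter-free three-branch gate over the (H,W), (H,C) and
(C,W) planes; each branch compresses the remaining axis with Z-Pool
(`[max, mean]`), convolves with a single 7×7 kernel, applies a sigmoid and
multiplies; branches are averaged. One module costs exactly
`3·(2·7² + 2) = 300` trainable scalars regardless of width.

The attention gate suppresses irrelevant skip-feature regions:
`α = σ(ψ(ReLU(W_x·skip + W_g·gate)))`, output `skip ⊙ α`.

Networks are trained with Adam (lr 0.001, batch 12) on mean pixelwise binary
cross-entropy, and evaluated with IoU, Dice (DSC), precision and the
Hausdorff distance between foreground point sets. See the methods vignette
(`vignettes/methods.Rmd`) for every design decision and convention.

## Worked example

Build the full model and reproduce the ablation parameter table:

```r
library(dtaunet)
net <- make_variant(variant_spec(dcd_encoder = TRUE, dcd_decoder = TRUE,
                                 ta_encoder = TRUE, ta_decoder = TRUE),
                    network_config(), seed = 1)
net
#> <dta_net> arch=attention_unet dcd(enc=TRUE,dec=TRUE) ta(enc=TRUE,dec=TRUE)
#>   widths: 64-128-256-512-1024 | params: 35,641,436 (35.6414 M)

tab <- ablation_table(network_config(), seed = 1)
tab[, c("variant", "params_M", "delta_M")]
#>      variant params_M    delta_M
#>     baseline  34.8786
#>  dcd_encoder  35.3624 (+ 0.4838)
#>  dcd_decoder  35.1549 (+ 0.2763)
#>     dcd_both  35.6387 (+ 0.7601)
#>   ta_encoder  34.8801 (+ 0.0015)
#>   ta_decoder  34.8798 (+ 0.0012)
#>      ta_both  34.8813 (+ 0.0027)
#>     dta_unet  35.6414 (+ 0.7628)
#>         unet  31.0435 (- 3.8351)
```

The baseline Attention U-Net counts 34.8786 M trainable parameters; adding
TA everywhere costs +0.0027 M (9 modules × 300 scalars), DCD everywhere
+0.7601 M, and the full DTA-UNet +0.7628 M; the plain U-Net comparison model
has 31.0435 M.

Generate a phantom dataset, train a width-reduced DTA-UNet for a few minutes
on CPU, and check that it fits its own training data:

```r
spec <- phantom_spec(image_size = 64, radius_range = c(3, 14),
                     background_texture_scale = 3, seed = 42)
generate_dataset(10, spec, split_ratio = 0.8, out_dir = "demo-data")

cfg <- network_config(widths = c(16, 32, 64, 128, 256))
net <- make_variant(variant_spec(TRUE, TRUE, TRUE, TRUE), cfg, seed = 42)
res <- train(net, "demo-data/manifest.json",
             train_config(epochs = 80, batch_size = 8, seed = 42,
                          checkpoint_dir = "demo-run"))
res$history$loss[c(1, 80)]
#> [1] 0.8153 0.2997

rep <- evaluate(res$best_checkpoint,
                load_manifest("demo-data/manifest.json", "train"))
rep
#> <metric_report> 8 images | IoU 0.9180  DSC 0.9568  Pre 0.9252  HD 25.2299
```

The loss falls from 0.82 to 0.30 over 80 epochs and the network reaches a
training Dice of 0.96 — the standard sanity check that the dynamic layers,
attention blocks and gradients are wired correctly. (Generalization to the
held-out split needs more than 8 training images; the test suite runs the
full overfit protocol at 16 images and 200 epochs.)

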