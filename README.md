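# xfctdn — low-dose XFCT image denoising with a Swin-Conv UNet

X-ray fluorescence computed tomography (XFCT) maps a high-Z contrast agent
(here gadolinium, K-alpha ≈ 43 keV) at high resolution, but benchtop sources
buy sensitivity with radiation dose: fewer photons per pixel — whether from
dose reduction or from narrower spectral bins — push the reconstructed slice
into severe Poisson noise on top of a Compton-scatter background. `xfctdn`
is an R toolkit for studying learned denoising in exactly this regime. It
provides:

* **Simulation** — hexagonal water phantoms (50 mm maximum diameter) with
  circular Gd tube inserts (8 mm, 0–3.1 mg/mL), rendered as expected-count
  images, Poisson-sampled per energy-bin width (0.05/0.1/0.5 keV) and
  dose-reduced by binomial photon thinning (noise level L% = fraction of
  photons removed), with rotation augmentation and a stratified 80/20
  hold-out.
* **The denoiser** — a four-scale UNet of swin-conv (SC) blocks,

  ```
  x1, x2 = Split(Conv1x1(x))
  z      = Conv1x1(Concat(SwinT(x1), RConv(x2))) + x
  ```

  combining windowed multi-head self-attention (SwinT, non-local) with a
  residual convolution branch (RConv, local); channels 64/128/256/512, four
  SC blocks per scale, 2×2 strided/transposed convolutions between scales.
  Forward *and backward* passes are implemented natively (RcppArmadillo
  kernels + hand-written gradients, verified by finite differences), so
  training needs no external deep-learning framework.
* **Training** — Adam under the schedule `lr(e) = lr0·decay^e`
  (defaults 1e-4, 0.9, 40 epochs, batch 2), a compound shape-aware loss
  `L1 + α(1−SSIM) + β·mean(W⊙|Δ|)` with `W` the target's normalized
  gradient-magnitude map, best-validation checkpointing, and fine-tuning
  from checkpoints (the train-at-25%-first, adapt-to-other-levels recipe).
* **Benchmarking** — reference PSNR/SSIM implementations (oracle-tested), a
  denoiser registry (`identity`, `nlm`, `bm3d`, `dncnn`, `scunet`,
  `proposed`, plus plug-ins), mean-per-cell tables over the
  (bin width × noise level) grid, CSV/Markdown reports and qualitative PNG
  panels.

## Worked example

Desk scale: 16 phantoms at 64×64, 75% dose reduction in the reference
0.5 keV bin, tiny SC-UNet preset (16/32/64/128 channels, ~348k parameters),
3 epochs.

```r
library(xfctdn)

specs <- lapply(1:16, function(i) random_phantom_spec(c(64L, 64L),
                                                      seed = child_seed(7, i)))
ds  <- build_dataset(specs, noise_levels = 75, bin_widths = 0.5, seed = 7)
tr  <- dataset_pairs(ds, "train"); te <- dataset_pairs(ds, "test")
val <- tr[1:6]; tr <- tr[-(1:6)]

model <- scunet_build(scunet_tiny_config(), seed = 7)
fit <- train_denoiser(model, tr, val,
                      train_config(lr0 = 2e-3, epochs = 3, seed = 7))

records <- rbind(evaluate_method("identity", te),
                 evaluate_method("nlm", te),
                 evaluate_method("proposed", te, ctx = list(model = fit$model)))
tab <- build_tables(records)
tab$psnr
```

```
#> # A tibble: 1 x 5
#>   bin_width noise_level identity   nlm proposed
#>       <dbl>       <dbl>    <dbl> <dbl>    <dbl>
#> 1       0.5          75     19.1  19.0     32.0
```

Read: on held-out phantoms the noisy 75%-reduced input sits near 19 dB PSNR
against the full-dose reference (`identity` is the no-denoising floor).
Because normalization is shared across dose levels, the low-dose input is
also 4× too dark — a brightness deficit that smoothing alone (NLM) cannot
repair, which is why it stays at the floor — while the trained SC-UNet
restores both brightness and structure at ~32 dB. The matching SSIM table
(`tab$ssim`) reads 0.332 / 0.290 / 0.803. `autoplot(tab)` draws the grid and
`render_panels()` writes side-by-side image comparisons.

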