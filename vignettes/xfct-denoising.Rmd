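---
title: "Simulating and denoising low-dose XFCT slice images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and denoising low-dose XFCT slice images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

X-ray fluorescence computed tomography (XFCT) images the distribution of a
high-Z contrast agent — here gadolinium, whose K-alpha fluorescence sits near
43 keV — by exciting it with an external X-ray beam and imaging the emitted
fluorescence photons. The dominant nuisance is Compton-scattered primary
photons landing in the fluorescence energy window, and the photon budget is
set by the radiation dose: reducing dose, or narrowing the spectral bin from
which the image is formed, reduces the counts per pixel and drives the image
into the Poisson-noise regime. `xfctdn` provides, in one package:

* a synthetic generator for the canonical benchtop scene — a water-filled
  hexagonal container (50 mm maximum diameter) with circular Gd tube inserts
  (8 mm diameter, concentrations 0-3.1 mg/mL);
* a physically faithful dose/bin-width degradation protocol;
* a hybrid Swin-transformer/convolutional UNet (SC-UNet) denoiser with a
  from-scratch training loop (Adam, compound shape-aware loss);
* classical baselines (non-local means, a simplified BM3D, DnCNN) behind one
  denoiser registry; and
* PSNR/SSIM benchmarking over the (bin width × noise level) grid.

## The simulation model

`render_phantom()` paints expected counts per pixel: `water_level` inside a
flat-top regular hexagon, a diffuse `compton_level` over the whole field of
view, and `signal_gain * concentration` on each tube disc, followed by a
Gaussian point-spread blur (`psf_sigma`, default 1 px). Membership is decided
at pixel centers, with no sub-pixel weighting. Units are expected counts at
the reference exposure: full dose, 0.5 keV bin.

Defaults place the scene at a 64 mm field of view, so a 64-px image has 1 mm
pixels, the hexagon has a 25 px circumradius and tubes have 4 px radius. The
intensity scale — `water_level = 20`, `compton_level = 5`,
`signal_gain = 65000` (so a 3.1 mg/mL tube adds about 200 counts/pixel) — was
chosen once to reproduce the qualitative regime of benchtop acquisitions:
tubes clearly visible at full dose, strongly degraded at 75% dose reduction
in narrow bins, with per-pixel counts in the tens. These are the package's
standing study conditions; tests and the acceptance script do not revisit
them.

Degradation has two independent axes:

* **Bin width.** Counts scale by `bin_width / 0.5`; a 0.05 keV bin has 10×
  fewer entries than the 0.5 keV reference. Spectral peak shapes are *not*
  simulated — the bin width acts purely as a multiplicative expected-count
  factor.
* **Dose.** `sample_counts()` draws `Poisson(lambda)` pixels at full dose;
  `thin_counts()` then keeps each photon independently with probability
  `keep = 1 - L/100` (binomial thinning). A noise level labelled "L%" is the
  percentage of photons *removed*. Thinning a Poisson image gives exactly the
  Poisson image of the reduced dose, which is why this is the physically
  correct dose model (the property tests verify the variance/mean ratio and
  the thinning composition law).

`build_dataset()` pairs the normalized thinned image (input) with the
normalized *full-dose* image of the same geometry (target) — matching a
protocol in which the high-dose acquisition is the reference — augments by
the three axis-aligned rotations (90/180/270 degrees, a 4× multiplicity; the
only augmentation implemented, since the rotation set is the only one that is
lossless on the pixel grid), and holds out `round(0.2 * N)` pairs per
(noise level, bin width) category. Normalization is fixed-range with `cmax`
the 99.5th percentile of the full-dose counts, computed per bin width and
shared across dose levels, so dose reduction visibly darkens the input — the
network therefore learns dose restoration as well as denoising.
All randomness derives from one master seed through the documented
`child_seed()` counter scheme, making the dataset a pure function of
(specs, grids, seed). The split is drawn at pair level within each category;
rotated copies of one phantom can therefore land on both sides of the split,
which is acceptable for synthetic benchmarking but should be tightened to
phantom-level grouping for real data.

## The network

The SC-UNet is a four-scale UNet whose basic unit, the swin-conv (SC)
block, computes

```
x1, x2 = Split(Conv1x1(x))
z      = Conv1x1(Concat(SwinT(x1), RConv(x2))) + x
```

with `SwinT` a shifted-window transformer block (layer norm, windowed
multi-head self-attention, layer norm, GELU MLP, both residual) and `RConv`
the residual convolution `x + Conv3x3(ReLU(Conv3x3(x)))`. Scales hold
64/128/256/512 channels with four SC blocks each; 2×2 strided convolutions
downscale, 2×2 transposed convolutions upscale, and additive skip
connections join matching scales. Attention windows are 8×8 with head
dimension 32 and MLP ratio 4; within each run of SC blocks the window shift
alternates 0, w/2, 0, w/2, and shifted windows carry the standard additive
mask that forbids attention across the cyclic wrap boundary. Relative
position bias is omitted in favour of plain windowed attention; the choice
is recorded in the configuration so results are self-describing. Inputs of
any size are reflect-padded to a multiple of `8 * window` and cropped back.

Because no deep-learning framework is available to R here, the forward and
backward passes are written by hand on top of small C++ kernels (im2col
convolution, per-window attention); every layer's gradient is verified
against central finite differences in the test suite. Initialization is
truncated normal (sd 0.02) for attention/MLP weights, Kaiming for
ReLU-followed convolutions, Xavier for linear ones, and 0.1× Xavier for each
SC block's fusion convolution — the small fusion gain keeps the deep
residual stack near-identity at initialization (unscaled initialization was
observed to blow up activations through the residual chains) while still
letting gradient reach every branch on the first step.

The `tiny` preset (channels 16/32/64/128, one SC block per scale, 4×4
windows, about 348k parameters) is the desk-scale configuration used
throughout the tests; the full configuration has about 17.9M parameters and
is exercised for construction and parameter-count checks only.

## Training

`train_denoiser()` runs Adam with the exponential schedule
`lr(e) = lr0 * decay^e` (zero-based epoch `e`; defaults `1e-4` and 0.9). A
per-*iteration* decay of 0.9 would extinguish the learning rate within one
epoch, so the decay is applied per epoch. Batch size defaults to 2.
Validation pairs are scored by PSNR/SSIM each epoch and the
best-validation-PSNR weights are kept; callers conventionally carve 10% of
the training split for validation, leaving the 20% hold-out untouched. The
multi-dose protocol — train at the 25% noise level first, then adapt to the
others — is expressed as successive calls whose later runs set
`finetune_from`, which loads the previous checkpoint's weights and never
re-initializes.

The compound loss is

```
L = L1 + alpha * (1 - SSIM(pred, target)) + beta * mean(W ⊙ |pred - target|)
```

where `W` is the target's gradient-magnitude map normalized to mean 1
(uniform for a constant target). This is this package's concrete
interpretation of a shape-aware compound loss — the weight map concentrates
the penalty on tube boundaries — with defaults `alpha = 0.5`, `beta = 1`;
`alpha = beta = 0` recovers plain L1. The SSIM term is differentiated
analytically (the gradient is checked numerically in the tests).

Desk-scale optimization uses a larger initial learning rate (`2e-3`) than
the full-scale protocol: with only a few hundred optimizer steps available,
`1e-4` barely moves a freshly initialized network, while the protocol's
value is appropriate for its 40-epoch, thousands-of-steps regime.

## Metrics

PSNR is `10 log10(R^2 / MSE)`; identical images report `Inf` in memory and
the string `"inf"` in CSV. SSIM follows the standard local-statistics form
with an 11×11 Gaussian window (sigma 1.5), `K1 = 0.01`, `K2 = 0.03`, valid
window positions only, and `data_range = 1` on normalized images; the
constants are recorded in every table's metadata. Both metrics are checked
against independently coded brute-force evaluations.

## Baselines

* **Non-local means** uses raw-patch squared distances on a reflect-padded
  image, `w = exp(-d / h^2)`, defaults patch radius 2 and search radius 7.
  The bandwidth defaults to `h = sigma_hat * sqrt(2 * Npatch)`, with
  `sigma_hat` the median-absolute-deviation estimate from the finest
  diagonal-detail band — pure-noise patch distances then receive weight
  near `exp(-1)`.
* **BM3D (simplified).** Two-stage collaborative filtering: grouping by mean
  squared block distance inside a search window, 2-D orthonormal DCT per
  block plus 1-D Haar across the (power-of-two) stack, hard threshold at
  `2.7 * sigma` with the DC coefficient exempt, aggregation weighted by
  1/(retained coefficients); the optional Wiener stage shrinks noisy
  coefficients by `p^2/(p^2 + sigma^2)` using the stage-1 pilot. This is a
  native simplified variant, not a reimplementation of the reference binary;
  an external implementation (including a volumetric BM4D) can be plugged in
  through `register_denoiser()`.
* **DnCNN** predicts the noise residual with 17 conv layers (64 channels).
  The middle layers use a learned per-channel affine in place of batch
  normalization — the form batch normalization takes at inference — since
  batch statistics at batch size 2 are degenerate; it is trained with the
  same pipeline and loss as the proposed model.

## Numerical and degenerate-input choices

* Thinning with `keep = 1` returns the input bit-identically; `keep = 0`
  returns an all-zero image.
* An all-zero image under per-image-max normalization returns zeros with a
  warning rather than dividing by zero.
* PSNR of identical images is `Inf`; table means exclude infinite entries
  and count them in the metadata.
* Layer-norm uses epsilon `1e-5`; attention masks use an additive `-1e9`.
* BM3D reference blocks always include the final row/column position so the
  whole image is covered regardless of stride.

## What the tests do and do not show

The test suite proves formula-level correctness (metric and NLM oracles,
dense-attention equivalence, gradient checks), the statistical laws of the
dose model, protocol fidelity (schedule, fine-tune start, table layout,
byte-level reproducibility), and that the trained tiny model beats the
no-denoising floor by several dB on held-out synthetic data at the 75%
reduction level (problem size: 128 pairs of 64×64 images, 5 epochs — the
sizes used by `scripts/acceptance.R` as well). They do not demonstrate
performance on real benchtop data: the generator omits detector response,
reconstruction and attenuation artifacts, pinhole-geometry blur and spectral
peak shapes, and the full-scale protocol (256×256 images, 64-512 channels,
40 epochs, fine-tuning across all noise levels) is far beyond desk scale.
Numbers produced at desk scale are therefore not comparable to published
full-scale results.
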