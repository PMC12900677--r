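---
title: "Structure-preserving super-resolution of retinal vasculature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-preserving super-resolution of retinal vasculature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalSR)
```

## The problem

Single-image super-resolution (SISR) reconstructs a high-resolution image
$I_{HR} \in \mathbb{R}^{H\times W\times C}$ from a low-resolution observation
$I_{LR} \in \mathbb{R}^{h\times w\times c}$ with $H = s\,h$, $W = s\,w$. The
forward model assumed throughout the package is

$$ I_{LR} = D(I_{HR}) + \eta, $$

with $D$ a degradation operator (here: bicubic downsampling followed by a
Gaussian blur of sd 1.0 applied to the downsampled image, switchable to the
blur-first convention via `prepareLR(preBlur = TRUE)`) and $\eta$ additive
noise.

For retinal fundus photographs the clinically critical content is the
vascular tree: its space-filling complexity (box-counting fractal dimension
$D_f$), its connectedness, and its tortuosity are diagnostic biomarkers.
Pixel metrics such as PSNR and SSIM are insensitive to small but clinically
meaningful distortions of these structures, so the package treats vascular
morphology as a first-class optimisation target and evaluation axis.

## The network

`srModel()` builds a dual-path residual network:

* **Shallow extraction** — one 3×3 convolution (reflective padding) maps the
  input to $d$ feature channels.
* **Transformer path** — `nRSTB` residual blocks, each a stack of
  `stlPerRSTB` shifted-window attention layers (pre-norm multi-head
  attention in non-overlapping `window`×`window` windows with learned
  relative position bias, alternating cyclic shifts of `window/2` with
  masked cross-window attention, then a pre-norm MLP of ratio `mlpRatio`),
  closed by a 3×3 convolution and a block-level residual.
* **CNN path** — `nRCAB` residual channel-attention blocks
  (conv–ReLU–conv, then a gate $\sigma(W_2\,\mathrm{ReLU}(W_1\,\mathrm{GAP}(F)))$
  applied channel-wise, residual add).
* **Fusion** — channel-wise concatenation of both path outputs, a pooled
  pyramid of `fusionScales` levels (average pooling by 1, 2, 4, …), a 1×1
  convolution per level back to $d$ channels, bilinear upsampling and
  summation.
* **Reconstruction** — per ×2 stage a 3×3 convolution to $4d$ channels and
  depth-to-space, then a final 3×3 convolution to image channels, added to
  the **bicubic global residual** `Upsample(I_LR)`.

The final convolution is zero-initialised, so an untrained model is exactly
the bicubic interpolator; training learns only the high-frequency residual.
Interior convolutions use zero padding (the standard choice in SR networks);
spatial dimensions are preserved through both paths and inputs of any size
are handled by internal padding to window multiples.

Two configuration notes where the design was genuinely open:

* The reference feature width is $d = 180$. A head count of 8 would give a
  non-integral head dimension, so the default is 6 heads (the choice of the
  window-attention restoration network this path follows at that width);
  likewise the channel-attention reduction defaults to $r = 12$, the nearest
  divisor of 180 to the RCAN convention of 16. Both are plain arguments.
* `tinyModelConfig()` ($d=16$, 1 RSTB × 2 STL, 2 RCAB, window 4, 2 heads,
  2 fusion scales) is the desk-scale preset used by the test-suite; it
  exercises every layer type on a single CPU.

All forward and backward passes are implemented in R on top of BLAS matrix
operations (im2col convolutions, per-window attention); every analytic
gradient is verified against finite differences in the test-suite.

## The composite loss

$$ L_\text{total} = \lambda_1 L_\text{MSE} + \lambda_2 L_\text{perceptual}
   + \lambda_3 L_\text{fractal}, \qquad
   (\lambda_1, \lambda_2, \lambda_3) = (1.0,\, 0.1,\, 0.05). $$

* $L_\text{MSE}$ — mean squared pixel error.
* $L_\text{perceptual}$ — mean squared feature distance through a fixed
  extractor, normalised by the feature-map size. The default extractor is a
  seeded random-weight two-layer 3×3 convolutional network, which keeps the
  package fully self-contained and deterministic; a pretrained backbone
  (e.g. VGG features) can be plugged in through
  `perceptualSpec(kind = "custom")`. Random shallow convolutional features
  are a recognised stand-in for trained features as a perceptual distance at
  small scale; they are *not* claimed to match a trained VGG.
* $L_\text{fractal} = |D_f(I_{HR}) - D_f(I_{SR})|$ — the structure term.

### The differentiable fractal surrogate

Box counting is a composition of thresholding, box occupancy tests, and a
log–log regression; only the regression is differentiable. `fractalLoss()`
therefore has two modes:

* **hard** (evaluation, logging, validation): vessel extraction
  (`extractVessels()`) followed by `boxCount()`; exact, non-differentiable.
* **soft** (training): every stage is replaced by a smooth counterpart.
  1. *Soft vessel probability*: $v = \sigma\!\big((\bar g_{25} - g - t_0)/\tau\big)$
     where $g$ is the green channel, $\bar g_{25}$ its reflect-padded 25×25
     local mean — the same operator the hard extractor thresholds — and
     $t_0 = 0.02$ the same offset. $\tau$ (default 0.05) is the temperature.
  2. *Soft box occupancy*: for each box of side $\varepsilon$, the noisy-OR
     $1 - \prod_{p \in \text{box}} (1 - v_p)$. As $\tau \to 0$ this
     converges to the hard occupancy indicator.
  3. *Soft dimension*: the closed-form least-squares slope of
     $\log N_\text{soft}(\varepsilon)$ against $\log 1/\varepsilon$ over
     dyadic $\varepsilon \in [1, \min(H,W)/4]$.

  Because the soft local mean equals the hard extractor's local mean
  operator exactly (including its reflective border handling), the $\tau \to 0$
  limit of the soft pipeline is the hard pipeline applied to the
  pre-morphology threshold mask; on binary calibration patterns the two
  losses agree to well under 0.01 at $\tau = 0.002$, and the test-suite
  asserts that convergence.

  The occupancy choice matters. A max-pooled occupancy (the most obvious
  smooth relaxation) routes each coarse level's entire gradient onto one
  argmax pixel per box; measured during development, those point gradients
  are two orders of magnitude larger per pixel than the MSE gradient and
  inject isolated-pixel artifacts that make the *hard* metric worse. The
  noisy-OR spreads the same signal across the whole box: direct gradient
  descent on the surrogate then demonstrably reduces the hard
  $\Delta D_f$ as well. This is the package's own design decision.

  Patches smaller than 32 px cannot support the three dyadic levels a slope
  needs; the term is skipped (0, with a warning) for such patches.

## Vascular evaluation metrics

* **`extractVessels()`** — green channel inverted, local-mean adaptive
  threshold (window 25 px, offset 0.02), morphological opening with a 3×3
  cross, components under 20 px removed, circular field of view (estimated
  from near-zero pixels, eroded for safety) excluded. The window/offset/
  component parameters are exposed; the defaults reach Dice ≥ 0.7 against
  the synthetic generator's exact ground truth.
* **`boxCount()`** — dyadic box sides from `minBox` to `maxBox`
  (zero-padding to a multiple of the largest box), occupancy counts, and the
  least-squares slope of $\log N$ vs $\log 1/\varepsilon$ with its $R^2$.
  An empty mask is an *error*, not dimension 0 — a silent zero would poison
  every downstream $\Delta D_f$. Estimates outside $[0, 2.2]$ are flagged.
* **$\Delta D_f$** (`deltaDf()`) — $|D_f(I_{HR}) - D_f(I_{SR})|$, both via
  the same extraction pipeline; clinical bins per `classifyDeltaDf()`:
  `[0, 0.01)` excellent, `[0.01, 0.05)` acceptable, `[0.05, 0.10)` moderate,
  `[0.10, ∞)` substantial.
* **VCI** (`vci()`) — the field names a Vessel Connectivity Index without a
  published formula; this package's operationalisation compares
  8-connected component counts of the two skeletons:
  $1 - |c_{SR} - c_{HR}| / \max(c_{SR}, c_{HR})$. Symmetric, in $[0,1]$,
  1 at identity.
* **VTP** (`vtp()`) — likewise an operationalisation: mean branch
  tortuosity (arc/chord over skeleton branches of ≥ 10 px, with branch
  points detected by crossing number ≥ 3 so staircase pixels do not
  fragment branches) compared as
  $\max(0,\, 1 - |\bar\tau_{SR} - \bar\tau_{HR}|/\bar\tau_{HR})$.

Both VCI and VTP are documented prominently as package-defined formulas;
they should not be compared numerically against other implementations of
the same names.

## Synthetic data

`generateFundus()` renders what the metrics need and nothing more: a dark
circular field of view, a bright mottled background, and recursively
branching vessel trees rooted on the rim, growing inward with seeded heading
jitter, per-segment sinusoidal wobble (`tortuosityAmp`), width decay per
branching level, and darker-than-background strokes written to RGB at
relative strengths (0.8, 1.0, 0.6) so the green channel carries the most
contrast, as in real fundus photographs. The image is anti-aliased; the
mask is the hard rasterisation of the same strokes — exact ground truth by
construction. Everything is bit-deterministic per seed.

Default parameters (256 px, 4 arcades, 5 branching levels, branch
probability 0.35, initial width 4 px decaying by 0.75, wobble 2 px,
background 0.75, vessel darkness 0.45, texture noise sd 0.02) were chosen
once to visually and morphologically resemble a mid-resolution fundus
photograph (vessel density a few percent of the field of view, mask
dimension ≈ 1.3–1.5).

What the generator deliberately does not emulate: pathology
(microaneurysms, exudates), the optic disc and macula, camera vignetting
and chromatic aberration, and real inter-eye anatomical variability.
Passing tests on synthetic data therefore demonstrate the correctness of
the algorithms and the direction of the training effects, not clinical
performance on real fundus images.

`generateCalibration()` provides analytic anchors for the box counter: a
line (dimension 1), a filled square (2), a unit-cell checkerboard (2), and
a Sierpinski triangle ($\log 3/\log 2 \approx 1.585$). With `iterations`
subdivision levels the Sierpinski cells are filled squares of side
$\text{size}/2^\text{iterations}$; fitting over boxes no smaller than that
cell recovers the analytic dimension exactly (finer boxes measure the
filled-cell rendering, whose dimension is 2 — the returned `minBox` records
the natural lower cut-off).

## Degradation protocols

`protocolSuite()` returns the six robustness protocols with their standard
parameters: Gaussian blur σ = 1.2; motion blur, 11-px kernel at 45°
(midpoint-rasterised line, step scaled so the kernel spans 11 taps along
its dominant axis, normalised to unit sum); Gaussian noise σ = 25 on the
8-bit scale (applied as σ/255 on [0,1], seeded); JPEG at quality 20 through
the baseline codec; 30 % radial vignetting ($1 - 0.3 (r/r_\text{max})^2$
with $r_\text{max}$ the half-diagonal); and a combined protocol. The
combined order — blur → noise → JPEG → vignette — follows the physical
acquisition chain (optics, sensor, compression, display) and is
configurable, as no canonical order is established. The noise severity
ladder for sweeps is σ ∈ {0, 10, 25, 35, 50}; the "low" rung is fixed at 10
as a package choice.

## Training

`trainModel()` is seeded Adam (β = 0.9/0.999, ε = 1e-8) on randomly
cropped, augmented LR/HR patch pairs with the cosine schedule

$$ \eta_t = \eta_\text{min} + \tfrac12 (\eta_\text{max} - \eta_\text{min})
   \big(1 + \cos(t \pi / T)\big), $$

$t$ indexed in epochs, $\eta_\text{max} = 2\times10^{-4}$,
$\eta_\text{min} = 10^{-6}$ (the minimum is a package default; only the
maximum is prescribed). Augmentation applies the same seeded transform to
both patches: flips (p = 0.5 each), rotation by a uniform multiple of 90°,
and identical ±5 % brightness/contrast jitter. LR patches are synthesised
from HR patches on the fly under a two-phase curriculum: before
`curriculumSwitch` (default 0.3) of the schedule only the base pipeline
(bicubic + blur σ = 1.0) is used; afterwards a per-sample draw adds one of
{blur σ ≤ 1.2, noise σ ≤ 25, JPEG q ≥ 20} at a sampled sub-protocol
severity. The phase boundary, menu and severities are package choices — the
progressive strategy is described qualitatively in the literature this
follows, without numeric values.

The loss is computed on the raw, unclipped network output (clipping only at
export) so gradients survive saturation. Validation runs per epoch (PSNR,
SSIM, optionally hard-mode $\Delta D_f$ — never the soft surrogate).
Checkpoints store the optimiser moments and the RNG state, so an
interrupted run resumed from `last.rds` reproduces the uninterrupted run
bit for bit (asserted in the tests).

### Desk-scale experiment sizes

The full-scale reference training (d = 180, 300 epochs, batch 16, 64-px
patches, 50 000 patch pairs, GPU) is out of scope by design. The package's
own experiments, sized for a single CPU core and used by the acceptance
checks, are:

* **Bicubic-margin run**: tiny preset, 2×, 96-px synthetic images, 16-px LR
  patches, batch 2, 2 000 optimiser steps. A fresh model starts exactly at
  the bicubic baseline; this run ends ≥ 0.5 dB above it.
* **Fractal-loss ablation**: because the structure term is a refinement on
  top of a pixel-faithful reconstruction (at full scale it is trained
  jointly for hundreds of epochs), the desk-scale ablation warm-starts both
  arms from one shared MSE-only checkpoint and RNG state, then continues
  with $\lambda_3 = 0.05$ versus $\lambda_3 = 0$ on identical batch
  sequences; validation $\Delta D_f$ (hard mode, averaged over the last
  epochs) is compared per seed, majority over five seeds. Branching from a
  common warm start isolates the term's effect from early-training noise,
  which otherwise swamps it at this scale.
* **Dual-path ablation**: tiny dual model versus transformer-only
  (`nRCAB = 0`) and CNN-only (`nRSTB = 0`) variants at an equal step
  budget (1 200 steps) with the degradation curriculum active, majority
  over five seeds. A disabled path contributes nothing to fusion — the
  single-path variants really are single paths, not "single path plus a
  shallow-feature skip". These are directional reproductions; effect sizes
  at this scale are tenths of a dB, far from the full-scale gaps, and the
  compact CNN-only variant remains genuinely competitive at this budget.

## Numerical choices and edge cases

* Bicubic resampling is the Keys kernel (a = −0.5), centre-aligned, with
  clamped borders and imresize-style kernel widening when downscaling; rows
  of the operator sum to one, so constants are preserved exactly.
* Gaussian blur is separable, reflect-padded, truncated at 3σ and
  renormalised; σ = 0 is the identity.
* 8-bit/16-bit quantisation is round-half-away-from-zero
  (`floor(v·maxval + 0.5)`); 0.5 stores as 128 at 8 bits.
* PSNR of identical images is the `Inf` sentinel, serialised as the string
  `"Inf"` in JSON reports, never a float overflow. PSNR/SSIM are computed
  on RGB in [0,1]; SSIM reduces RGB to Rec. 601 luminance first. A
  luminance-channel PSNR convention can be layered on via `toGray()`.
* Box-count fits require ≥ 3 dyadic levels; `boxCount()` errors rather than
  extrapolate from fewer.
* Empty masks: extraction of a contrast-free image warns and returns an
  empty mask; all mask metrics refuse empty inputs with errors.
* The skeletonizer is Zhang–Suen thinning; branch decomposition removes
  crossing-number junctions, traces each remaining path from an endpoint,
  and measures arc length with √2 diagonal steps. Closed loops (no
  endpoint) are skipped.

## Known limitations

* The perceptual default is a random-feature extractor, not a pretrained
  backbone; perceptual-loss ablations therefore probe the mechanism, not
  VGG-specific behaviour.
* VCI/VTP are package-defined formulas for named-but-undefined metrics.
* The R implementation favours clarity and exactness over speed; the full
  d = 180 configuration forward-passes fine but is not practical to train
  in R. The tiny preset is the supported training scale.
* Synthetic-data realism bounds what the directional experiments can show
  (see above); absolute benchmark values from real datasets are not
  reproducible here and are used only as printed inputs to the reporting
  utilities.
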