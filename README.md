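# fractalSR

Structure-preserving super-resolution of retinal fundus images, with
vascular morphology as a first-class objective and evaluation axis.

## The problem

Low-resolution fundus photographs — from legacy cameras, telemedicine
compression, or bandwidth-limited screening programmes — obscure the fine
vasculature that diabetic-retinopathy diagnosis depends on. Generic
super-resolution either over-smooths vessels (CNN regression) or risks
hallucinating them (GANs). Neither failure shows up in PSNR/SSIM, but both
corrupt the morphology clinicians read: vascular complexity (box-counting
fractal dimension *D*<sub>f</sub>), network connectedness, and vessel
tortuosity.

This package implements, end to end and self-contained in R:

* a **dual-path residual network**: a shifted-window self-attention
  (transformer) path for global context in parallel with a residual
  channel-attention CNN path for local vessel detail, joined by pooled
  multi-scale fusion and sub-pixel reconstruction over a bicubic global
  residual (`srModel()`, `srForward()`, `trainModel()`) — forward *and*
  hand-derived backward passes, verified against finite differences;
* a **composite loss**
  *L* = λ₁·MSE + λ₂·perceptual + λ₃·|*D*<sub>f</sub>(HR) − *D*<sub>f</sub>(SR)|
  with weights (1.0, 0.1, 0.05) and a differentiable noisy-OR box-counting
  surrogate for the fractal term (`totalLoss()`, `fractalLoss()`);
* **vascular metrics**: vessel extraction, box-counting fractal dimension
  with analytic calibration patterns, ΔD<sub>f</sub> with clinical bins
  (&lt;0.01 excellent / &lt;0.05 acceptable / &lt;0.10 moderate / ≥0.10
  substantial), vessel connectivity and tortuosity preservation
  (`extractVessels()`, `boxCount()`, `deltaDf()`, `vci()`, `vtp()`);
* the **six-protocol degradation suite** for robustness studies — Gaussian
  blur σ 1.2, 11-px motion blur at 45°, Gaussian noise σ 25, JPEG quality
  20, 30 % vignetting, and their combination (`protocolSuite()`);
* a **synthetic fundus generator** with exact vessel ground truth, so every
  stage is testable without downloading clinical data (`generateFundus()`).

See the methods vignette (`vignettes/structure-preserving-sr.Rmd`) for the
model, the surrogate-loss design, and every numerical choice.

## Worked example

```r
library(fractalSR)

# a synthetic fundus image with exact vessel ground truth
fun  <- generateFundus(vesselTreeParams(seed = 1))
fun
#> SyntheticFundus 256x256, 2239 vessel pixels (3.4%)

mask <- extractVessels(fundusImage(fun))
diceOverlap(mask, vesselMask(fun))
#> [1] 0.863

boxCount(vesselMask(fun))
#> BoxCountResult: df = 1.2894 (R2 = 0.9987) over 8 box sizes [1..128]

# degrade to LR, "reconstruct" with plain bicubic, and evaluate
lr <- prepareLR(fundusImage(fun), s = 2)
sr <- bicubicResize(lr, 256, 256)
evaluatePair(fundusImage(fun), sr)
#> MetricReport: PSNR 23.75 dB | SSIM 0.7744 | dDf 0.0819 | VCI 0.8571 | VTP 0.7773 [moderate]
```

Reading this: the generated image has a vascular tree of fractal dimension
1.29 (healthy retinal values are ~1.45; the desk-scale tree is a little
sparser). The bicubic reconstruction loses fine-scale vessels, shifting the
fractal dimension by 0.082 — in the *moderate* clinical band — while a ~24
dB PSNR looks unremarkable; that dissociation is exactly why the vascular
metrics exist. Training the network (`trainModel()` with
`tinyModelConfig()`) starts from this bicubic baseline — the reconstruction
conv is zero-initialised — and improves on it within a few hundred CPU
steps.

A thin command-line wrapper over the same functions ships in
`inst/cli/fractalsr` (`generate`, `degrade`, `train`, `enhance`,
`evaluate`).

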