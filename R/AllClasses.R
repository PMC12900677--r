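#' @import methods
NULL

## ---- ModelConfig ---------------------------------------------------------

#' Network configuration
#'
#' Hyper-structure of the dual-path super-resolution network: upscaling
#' factor, feature width, depth of the transformer and CNN paths, window
#' attention geometry, channel-attention bottleneck, and fusion pyramid depth.
#' The reference configuration mirrors the full model (feature dimension 180,
#' 6 residual transformer blocks of 6 layers, 8 channel-attention blocks,
#' 8x8 windows). Head count defaults to 6 and the channel-attention
#' reduction to 12, the nearest divisors of 180 (the head dimension must be
#' integral); [tinyModelConfig()] is a desk-scale preset used throughout the
#' test-suite.
#'
#' @slot scale integer, upscaling factor (2 or 4).
#' @slot featureDim integer, channels `d` of every intermediate feature map.
#' @slot nRSTB integer, residual transformer blocks in the transformer path
#'   (0 disables the path for ablations; the path then passes features
#'   through unchanged).
#' @slot stlPerRSTB integer, attention layers per transformer block.
#' @slot nRCAB integer, residual channel-attention blocks in the CNN path.
#' @slot window integer, attention window side in pixels.
#' @slot heads integer, attention heads (`d` must be divisible).
#' @slot mlpRatio numeric, hidden expansion of the per-layer MLP.
#' @slot caReduction integer, channel-attention bottleneck reduction `r`.
#' @slot fusionScales integer, levels of the pooled fusion pyramid.
#' @slot inChannels integer, image channels (1 or 3).
#' @export
setClass("ModelConfig", representation(
  scale = "integer", featureDim = "integer", nRSTB = "integer",
  stlPerRSTB = "integer", nRCAB = "integer", window = "integer",
  heads = "integer", mlpRatio = "numeric", caReduction = "integer",
  fusionScales = "integer", inChannels = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@scale %in% c(2L, 4L)) msg <- c(msg, "scale must be 2 or 4")
  if (object@featureDim %% object@heads != 0L)
    msg <- c(msg, "featureDim must be divisible by heads")
  if (object@featureDim %% object@caReduction != 0L)
    msg <- c(msg, "featureDim must be divisible by caReduction")
  if (object@window < 2L) msg <- c(msg, "window must be >= 2")
  if (any(c(object@stlPerRSTB, object@heads, object@fusionScales) < 1L))
    msg <- c(msg, "layer/head counts must be >= 1")
  if (object@nRSTB < 0L || object@nRCAB < 0L || object@nRSTB + object@nRCAB < 1L)
    msg <- c(msg, "need nRSTB, nRCAB >= 0 with at least one path non-empty")
  if (!object@inChannels %in% c(1L, 3L)) msg <- c(msg, "inChannels must be 1 or 3")
  if (length(msg)) msg else TRUE
})

#' @param scale,featureDim,nRSTB,stlPerRSTB,nRCAB,window,heads,mlpRatio,caReduction,fusionScales,inChannels
#'   See the slot documentation.
#' @rdname ModelConfig-class
#' @export
modelConfig <- function(scale = 2L, featureDim = 180L, nRSTB = 6L,
                        stlPerRSTB = 6L, nRCAB = 8L, window = 8L, heads = 6L,
                        mlpRatio = 2, caReduction = 12L, fusionScales = 3L,
                        inChannels = 3L) {
  new("ModelConfig", scale = as.integer(scale), featureDim = as.integer(featureDim),
      nRSTB = as.integer(nRSTB), stlPerRSTB = as.integer(stlPerRSTB),
      nRCAB = as.integer(nRCAB), window = as.integer(window),
      heads = as.integer(heads), mlpRatio = as.numeric(mlpRatio),
      caReduction = as.integer(caReduction), fusionScales = as.integer(fusionScales),
      inChannels = as.integer(inChannels))
}

#' Desk-scale network preset
#'
#' Sixteen feature channels, one transformer block of two layers, two
#' channel-attention blocks, 4x4 windows, two heads. Small enough to train on
#' one CPU core in seconds per hundred steps while exercising every layer
#' type of the full architecture.
#'
#' @param scale Upscaling factor (default 2).
#' @param inChannels Image channels (default 3).
#' @return A [ModelConfig-class] object.
#' @export
tinyModelConfig <- function(scale = 2L, inChannels = 3L) {
  modelConfig(scale = scale, featureDim = 16L, nRSTB = 1L, stlPerRSTB = 2L,
              nRCAB = 2L, window = 4L, heads = 2L, mlpRatio = 2,
              caReduction = 4L, fusionScales = 2L, inChannels = inChannels)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: x%d SR | d=%d | %d RSTB x %d STL | %d RCAB | window %d, %d heads | fusion %d scales\n",
    object@scale, object@featureDim, object@nRSTB, object@stlPerRSTB,
    object@nRCAB, object@window, object@heads, object@fusionScales))
})

## ---- SRModel -------------------------------------------------------------

#' A super-resolution model: configuration plus learnable weights
#'
#' @slot config A [ModelConfig-class].
#' @slot params Named list of weight arrays (see [initParameters()]).
#' @slot meta List with bookkeeping (init seed, training epoch, format version).
#' @export
setClass("SRModel", representation(
  config = "ModelConfig", params = "list", meta = "list"))

setValidity("SRModel", function(object) {
  bad <- vapply(object@params, function(p) any(!is.finite(p)), logical(1))
  if (any(bad)) paste("non-finite weights in:", paste(names(bad)[bad], collapse = ", "))
  else TRUE
})

setMethod("show", "SRModel", function(object) {
  cat("SRModel with", length(object@params), "weight tensors,",
      format(countParameters(object@config), big.mark = ","), "parameters\n")
  show(object@config)
  if (!is.null(object@meta$epoch)) cat("trained epochs:", object@meta$epoch, "\n")
})

#' @rdname SRModel-class
#' @param object An `SRModel`.
#' @export
modelCfg <- function(object) object@config

#' @rdname SRModel-class
#' @export
modelParams <- function(object) object@params

## ---- BoxCountResult ------------------------------------------------------

#' Box-counting result
#'
#' Box sizes, occupancy counts, the fitted fractal dimension (slope of
#' log N(eps) against log(1/eps)), and the fit quality.
#'
#' @slot boxSizes Numeric vector of box sides in pixels (powers of two).
#' @slot counts Integer vector, occupied boxes per size.
#' @slot df Numeric, fitted dimension.
#' @slot fitR2 Numeric, R-squared of the log-log fit.
#' @slot flagged Logical, `TRUE` when `df` falls outside `[0, 2.2]`.
#' @export
setClass("BoxCountResult", representation(
  boxSizes = "numeric", counts = "numeric", df = "numeric",
  fitR2 = "numeric", flagged = "logical"))

setValidity("BoxCountResult", function(object) {
  msg <- character()
  if (length(object@boxSizes) != length(object@counts))
    msg <- c(msg, "boxSizes and counts differ in length")
  if (any(object@counts <= 0)) msg <- c(msg, "counts must be positive")
  if (is.unsorted(rev(object@counts)) && is.unsorted(object@counts))
    msg <- msg  # counts ordering checked against sizes below
  o <- order(object@boxSizes)
  if (any(diff(object@counts[o]) > 0))
    msg <- c(msg, "counts must be non-increasing in box size")
  if (!is.finite(object@df)) msg <- c(msg, "df must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BoxCountResult", function(object) {
  cat(sprintf("BoxCountResult: df = %.4f (R2 = %.4f) over %d box sizes [%d..%d]%s\n",
              object@df, object@fitR2, length(object@boxSizes),
              min(object@boxSizes), max(object@boxSizes),
              if (object@flagged) " [flagged: df outside [0, 2.2]]" else ""))
})

#' @rdname BoxCountResult-class
#' @param object A `BoxCountResult`.
#' @export
fractalDim <- function(object) object@df

## ---- VesselTreeParams / SyntheticFundus ----------------------------------

#' Parameters of the synthetic vascular tree generator
#'
#' @slot seed integer RNG seed; identical parameters give bit-identical output.
#' @slot imageSize integer, square image side in pixels.
#' @slot fovRadiusFrac numeric in (0,1], field-of-view radius as a fraction of
#'   half the image side.
#' @slot nRoots integer, vessel trees rooted on the field-of-view rim.
#' @slot maxDepth integer, branching levels.
#' @slot branchProb numeric, probability a segment bifurcates.
#' @slot angleJitter numeric, radians of random heading perturbation.
#' @slot initialWidth numeric, root vessel width in pixels.
#' @slot widthDecay numeric in (0,1), width multiplier per level.
#' @slot tortuosityAmp numeric, sinusoidal lateral wobble amplitude in pixels.
#' @slot backgroundLevel numeric in [0,1], fundus background brightness.
#' @slot vesselDarkness numeric in [0,1], vessel darkness below background.
#' @slot textureNoiseSd numeric, additive texture noise standard deviation.
#' @export
setClass("VesselTreeParams", representation(
  seed = "integer", imageSize = "integer", fovRadiusFrac = "numeric",
  nRoots = "integer", maxDepth = "integer", branchProb = "numeric",
  angleJitter = "numeric", initialWidth = "numeric", widthDecay = "numeric",
  tortuosityAmp = "numeric", backgroundLevel = "numeric",
  vesselDarkness = "numeric", textureNoiseSd = "numeric"))

setValidity("VesselTreeParams", function(object) {
  msg <- character()
  if (object@branchProb < 0 || object@branchProb > 1)
    msg <- c(msg, "branchProb must be in [0,1]")
  if (object@fovRadiusFrac <= 0 || object@fovRadiusFrac > 1)
    msg <- c(msg, "fovRadiusFrac must be in (0,1]")
  if (object@widthDecay <= 0 || object@widthDecay >= 1)
    msg <- c(msg, "widthDecay must be in (0,1)")
  if (object@initialWidth < 1) msg <- c(msg, "initialWidth must be >= 1 pixel")
  for (f in c("backgroundLevel", "vesselDarkness", "textureNoiseSd")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must be in [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @param seed,imageSize,fovRadiusFrac,nRoots,maxDepth,branchProb,angleJitter,initialWidth,widthDecay,tortuosityAmp,backgroundLevel,vesselDarkness,textureNoiseSd
#'   See slot documentation; defaults emulate a mid-resolution fundus
#'   photograph with four vessel arcades.
#' @rdname VesselTreeParams-class
#' @export
vesselTreeParams <- function(seed = 0L, imageSize = 256L, fovRadiusFrac = 0.95,
                             nRoots = 4L, maxDepth = 5L, branchProb = 0.35,
                             angleJitter = 0.35, initialWidth = 4,
                             widthDecay = 0.75, tortuosityAmp = 2,
                             backgroundLevel = 0.75, vesselDarkness = 0.45,
                             textureNoiseSd = 0.02) {
  new("VesselTreeParams", seed = as.integer(seed), imageSize = as.integer(imageSize),
      fovRadiusFrac = fovRadiusFrac, nRoots = as.integer(nRoots),
      maxDepth = as.integer(maxDepth), branchProb = branchProb,
      angleJitter = angleJitter, initialWidth = initialWidth,
      widthDecay = widthDecay, tortuosityAmp = tortuosityAmp,
      backgroundLevel = backgroundLevel, vesselDarkness = vesselDarkness,
      textureNoiseSd = textureNoiseSd)
}

setMethod("show", "VesselTreeParams", function(object) {
  cat(sprintf(
    "VesselTreeParams: %dpx, %d roots, depth %d, branchProb %.2f, wobble %.1fpx, seed %d\n",
    object@imageSize, object@nRoots, object@maxDepth, object@branchProb,
    object@tortuosityAmp, object@seed))
})

#' Synthetic fundus image with exact vessel ground truth
#'
#' @slot image `H x W x 3` array in [0,1].
#' @slot mask `H x W` binary matrix, 1 exactly where the hard-rasterised
#'   vessel stroke covers the pixel (0 outside the field of view).
#' @slot params The generating [VesselTreeParams-class].
#' @export
setClass("SyntheticFundus", representation(
  image = "array", mask = "matrix", params = "VesselTreeParams"))

setValidity("SyntheticFundus", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary")
  if (!identical(dim(object@image)[1:2], dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticFundus", function(object) {
  cat(sprintf("SyntheticFundus %dx%d, %d vessel pixels (%.1f%%)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              100 * mean(object@mask)))
})

#' @rdname SyntheticFundus-class
#' @param object A `SyntheticFundus`.
#' @export
fundusImage <- function(object) object@image

#' @rdname SyntheticFundus-class
#' @export
vesselMask <- function(object) object@mask

## ---- DegradationSpec -----------------------------------------------------

#' Image degradation specification
#'
#' One of seven degradation kinds with the parameters relevant to that kind.
#' `combined` composes `subSpecs` in order.
#'
#' @slot kind One of bicubic_down, gaussian_blur, motion_blur, gaussian_noise,
#'   jpeg, vignette, combined.
#' @slot scale Integer downsampling factor (bicubic_down).
#' @slot sigma Blur sd in pixels, or noise sd in 8-bit intensity units.
#' @slot kernelLen Odd motion-blur kernel length in pixels.
#' @slot angle Motion-blur angle in degrees.
#' @slot quality JPEG quality factor 1-100.
#' @slot strength Vignette strength in [0,1] at the image corner.
#' @slot seed Integer RNG seed (gaussian_noise).
#' @slot subSpecs List of `DegradationSpec` (combined).
#' @export
setClass("DegradationSpec", representation(
  kind = "character", scale = "integer", sigma = "numeric",
  kernelLen = "integer", angle = "numeric", quality = "integer",
  strength = "numeric", seed = "integer", subSpecs = "list"))

.deg_kinds <- c("bicubic_down", "gaussian_blur", "motion_blur",
                "gaussian_noise", "jpeg", "vignette", "combined")

setValidity("DegradationSpec", function(object) {
  msg <- character()
  if (!object@kind %in% .deg_kinds)
    msg <- c(msg, paste("unknown kind:", object@kind))
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@kernelLen < 1L || object@kernelLen %% 2L == 0L)
    msg <- c(msg, "kernelLen must be odd and >= 1")
  if (object@quality < 1L || object@quality > 100L)
    msg <- c(msg, "quality must be in [1,100]")
  if (object@strength < 0 || object@strength > 1)
    msg <- c(msg, "strength must be in [0,1]")
  if (object@kind == "combined" && !length(object@subSpecs))
    msg <- c(msg, "combined spec needs subSpecs")
  if (length(object@subSpecs) &&
      !all(vapply(object@subSpecs, is, logical(1), "DegradationSpec")))
    msg <- c(msg, "subSpecs must be DegradationSpec objects")
  if (length(msg)) msg else TRUE
})

#' @param kind,scale,sigma,kernelLen,angle,quality,strength,seed,subSpecs
#'   See slot documentation.
#' @rdname DegradationSpec-class
#' @export
degradationSpec <- function(kind, scale = 2L, sigma = 0, kernelLen = 1L,
                            angle = 0, quality = 90L, strength = 0,
                            seed = 0L, subSpecs = list()) {
  new("DegradationSpec", kind = kind, scale = as.integer(scale),
      sigma = as.numeric(sigma), kernelLen = as.integer(kernelLen),
      angle = as.numeric(angle), quality = as.integer(quality),
      strength = as.numeric(strength), seed = as.integer(seed),
      subSpecs = subSpecs)
}

setMethod("show", "DegradationSpec", function(object) {
  extra <- switch(object@kind,
    bicubic_down  = sprintf("x%d", object@scale),
    gaussian_blur = sprintf("sigma=%.2f", object@sigma),
    motion_blur   = sprintf("%dpx @ %.0f deg", object@kernelLen, object@angle),
    gaussian_noise = sprintf("sigma=%.0f/255, seed %d", object@sigma, object@seed),
    jpeg          = sprintf("q=%d", object@quality),
    vignette      = sprintf("strength=%.2f", object@strength),
    combined      = sprintf("%d sub-specs", length(object@subSpecs)))
  cat("DegradationSpec:", object@kind, paste0("(", extra, ")"), "\n")
})

## ---- TrainConfig / TrainHistory ------------------------------------------

#' Training configuration
#'
#' @slot etaMax,etaMin Maximum / minimum learning rate of the cosine schedule.
#' @slot epochs Total epochs `T` of the schedule.
#' @slot stepsPerEpoch Optimiser steps per epoch.
#' @slot batch Patch pairs per step.
#' @slot patch LR-side patch size in pixels.
#' @slot seed RNG seed for the whole run.
#' @slot curriculumSwitch Fraction of `epochs` after which harder
#'   degradations enter the LR synthesis.
#' @slot lossWeights Numeric `c(mse, perceptual, fractal)` weights.
#' @slot augmentFlips,augmentRotate,augmentJitter Augmentation toggles.
#' @slot beta1,beta2,adamEps Adam moment coefficients and epsilon.
#' @slot gradClip Gradient L2-norm clip (0 disables).
#' @slot valDeltaDf Also record validation fractal-dimension difference
#'   (hard, non-differentiable evaluation mode) each epoch.
#' @export
setClass("TrainConfig", representation(
  etaMax = "numeric", etaMin = "numeric", epochs = "integer",
  stepsPerEpoch = "integer", batch = "integer", patch = "integer",
  seed = "integer", curriculumSwitch = "numeric", lossWeights = "numeric",
  augmentFlips = "logical", augmentRotate = "logical", augmentJitter = "logical",
  beta1 = "numeric", beta2 = "numeric", adamEps = "numeric",
  gradClip = "numeric", valDeltaDf = "logical"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@etaMin < 0 || object@etaMin > object@etaMax)
    msg <- c(msg, "need 0 <= etaMin <= etaMax")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batch < 1L) msg <- c(msg, "batch must be >= 1")
  if (length(object@lossWeights) != 3L || any(object@lossWeights < 0))
    msg <- c(msg, "lossWeights must be 3 non-negative numbers")
  if (length(msg)) msg else TRUE
})

#' @param etaMax,etaMin,epochs,stepsPerEpoch,batch,patch,seed,curriculumSwitch,lossWeights,augmentFlips,augmentRotate,augmentJitter,beta1,beta2,adamEps,gradClip,valDeltaDf
#'   See slot documentation. Reference-run defaults: Adam at eta_max 2e-4
#'   annealed to 1e-6, batch 16, 64-pixel LR patches, loss weights
#'   (1.0, 0.1, 0.05).
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(etaMax = 2e-4, etaMin = 1e-6, epochs = 300L,
                        stepsPerEpoch = 100L, batch = 16L, patch = 64L,
                        seed = 0L, curriculumSwitch = 0.3,
                        lossWeights = c(1.0, 0.1, 0.05),
                        augmentFlips = TRUE, augmentRotate = TRUE,
                        augmentJitter = TRUE, beta1 = 0.9, beta2 = 0.999,
                        adamEps = 1e-8, gradClip = 0, valDeltaDf = FALSE) {
  new("TrainConfig", etaMax = etaMax, etaMin = etaMin, epochs = as.integer(epochs),
      stepsPerEpoch = as.integer(stepsPerEpoch), batch = as.integer(batch),
      patch = as.integer(patch), seed = as.integer(seed),
      curriculumSwitch = curriculumSwitch, lossWeights = as.numeric(lossWeights),
      augmentFlips = augmentFlips, augmentRotate = augmentRotate,
      augmentJitter = augmentJitter, beta1 = beta1, beta2 = beta2,
      adamEps = adamEps, gradClip = gradClip, valDeltaDf = valDeltaDf)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d epochs x %d steps, batch %d, patch %d | lr %.2g -> %.2g | weights (%.2g, %.2g, %.2g)\n",
    object@epochs, object@stepsPerEpoch, object@batch, object@patch,
    object@etaMax, object@etaMin, object@lossWeights[1], object@lossWeights[2],
    object@lossWeights[3]))
})

#' Per-epoch training records
#'
#' @slot records `data.frame` with columns epoch, lr, loss, lossMse,
#'   lossPerceptual, lossFractal, valPsnr, valSsim, valDeltaDf.
#' @export
setClass("TrainHistory", representation(records = "data.frame"))

setValidity("TrainHistory", function(object) {
  r <- object@records
  if (nrow(r) && any(diff(r$epoch) <= 0)) "epochs must be strictly increasing"
  else TRUE
})

setMethod("show", "TrainHistory", function(object) {
  r <- object@records
  cat("TrainHistory:", nrow(r), "epochs\n")
  if (nrow(r)) {
    last <- r[nrow(r), ]
    cat(sprintf("  final: loss %.5f, val PSNR %.2f dB\n", last$loss, last$valPsnr))
  }
})

#' @rdname TrainHistory-class
#' @param object A `TrainHistory`.
#' @export
historyRecords <- function(object) object@records

## ---- MetricReport --------------------------------------------------------

#' Image-pair evaluation report
#'
#' PSNR and SSIM for pixel fidelity plus the clinical vascular metrics:
#' fractal-dimension difference, vessel connectivity index, vessel tortuosity
#' preservation, and the clinical category of the fractal difference.
#' Identical image pairs get the infinite-PSNR sentinel `Inf`.
#'
#' @slot psnr Numeric, dB (possibly `Inf`).
#' @slot ssim Numeric in [-1, 1].
#' @slot deltaDf Numeric >= 0, or `NA` when not computed.
#' @slot vci,vtp Numeric in [0, 1], or `NA`.
#' @slot retentionPct Numeric percentage, or `NA`.
#' @slot clinicalCategory Character, one of excellent/acceptable/moderate/
#'   substantial, or `NA`.
#' @export
setClass("MetricReport", representation(
  psnr = "numeric", ssim = "numeric", deltaDf = "numeric", vci = "numeric",
  vtp = "numeric", retentionPct = "numeric", clinicalCategory = "character"))

setValidity("MetricReport", function(object) {
  msg <- character()
  if (!is.na(object@psnr) && !is.infinite(object@psnr) && object@psnr < 0)
    msg <- c(msg, "psnr must be >= 0 for distinct images")
  for (f in c("vci", "vtp")) {
    v <- slot(object, f)
    if (!is.na(v) && (v < 0 || v > 1)) msg <- c(msg, paste(f, "must be in [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @param psnr,ssim,deltaDf,vci,vtp,retentionPct,clinicalCategory See slots.
#' @rdname MetricReport-class
#' @export
metricReport <- function(psnr, ssim, deltaDf = NA_real_, vci = NA_real_,
                         vtp = NA_real_, retentionPct = NA_real_,
                         clinicalCategory = NA_character_) {
  new("MetricReport", psnr = psnr, ssim = ssim, deltaDf = deltaDf,
      vci = vci, vtp = vtp, retentionPct = retentionPct,
      clinicalCategory = clinicalCategory)
}

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: PSNR %s dB | SSIM %.4f | dDf %s | VCI %s | VTP %s%s\n",
              if (is.infinite(object@psnr)) "Inf" else sprintf("%.2f", object@psnr),
              object@ssim,
              if (is.na(object@deltaDf)) "NA" else sprintf("%.4f", object@deltaDf),
              if (is.na(object@vci)) "NA" else sprintf("%.4f", object@vci),
              if (is.na(object@vtp)) "NA" else sprintf("%.4f", object@vtp),
              if (is.na(object@clinicalCategory)) ""
              else paste0(" [", object@clinicalCategory, "]")))
})

#' Convert a MetricReport to a plain named list (JSON-ready)
#'
#' @param report A [MetricReport-class].
#' @return Named list with the metric fields; infinite PSNR is serialised as
#'   the string `"Inf"`.
#' @export
reportAsList <- function(report) {
  list(psnr = if (is.infinite(report@psnr)) "Inf" else report@psnr,
       ssim = report@ssim, delta_df = report@deltaDf, vci = report@vci,
       vtp = report@vtp, retention_pct = report@retentionPct,
       clinical_category = report@clinicalCategory)
}
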