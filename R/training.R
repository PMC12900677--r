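## Optimisation: cosine-annealed Adam, paired-patch sampling with
## augmentation, a two-phase degradation curriculum, per-epoch validation,
## and resumable checkpointing.

#' Cosine-annealed learning rate
#'
#' `eta_min + (eta_max - eta_min) * (1 + cos(t * pi / T)) / 2` with `t` in
#' epochs, so `t = 0` gives `eta_max` and `t = T` gives `eta_min`.
#'
#' @param t Epoch index, `0 <= t <= T`.
#' @param cfg A [TrainConfig-class].
#' @return Learning rate.
#' @export
cosineLR <- function(t, cfg) {
  if (t < 0 || t > cfg@epochs) stop("t out of [0, T]", call. = FALSE)
  cfg@etaMin + 0.5 * (cfg@etaMax - cfg@etaMin) * (1 + cos(t * pi / cfg@epochs))
}

#' Seeded paired augmentation
#'
#' Applies the same seeded transform to an aligned LR/HR patch pair:
#' horizontal and vertical flips (probability 0.5 each), rotation by a
#' uniform multiple of 90 degrees, and identical brightness/contrast jitter
#' of up to 5%, clipped to `[0, 1]`. All toggles off gives the identity.
#'
#' @param lrPatch,hrPatch Aligned patch pair.
#' @param seed Integer seed.
#' @param flips,rotate,jitter Toggles.
#' @return List `(lr, hr)` of transformed patches.
#' @export
augmentPair <- function(lrPatch, hrPatch, seed, flips = TRUE, rotate = TRUE,
                        jitter = TRUE) {
  withLocalSeed(seed, {
    lr <- asImage(lrPatch, check = FALSE); hr <- asImage(hrPatch, check = FALSE)
    if (flips) {
      if (stats::runif(1) < 0.5) { lr <- flipH(lr); hr <- flipH(hr) }
      if (stats::runif(1) < 0.5) { lr <- flipV(lr); hr <- flipV(hr) }
    }
    if (rotate) {
      k <- sample(0:3, 1)
      lr <- rot90Img(lr, k); hr <- rot90Img(hr, k)
    }
    if (jitter) {
      gain <- stats::runif(1, 0.95, 1.05)
      bias <- stats::runif(1, -0.05, 0.05)
      lr <- clip01((lr - 0.5) * gain + 0.5 + bias)
      hr <- clip01((hr - 0.5) * gain + 0.5 + bias)
    }
    list(lr = lr, hr = hr)
  })
}

#' Sample aligned LR/HR patch pairs
#'
#' LR crops of side `patch` at seeded uniform offsets; HR crops of side
#' `scale * patch` at exactly `scale` times those offsets.
#'
#' @param lr,hr An aligned LR/HR image pair.
#' @param n Number of patch pairs.
#' @param patch LR-side patch size in pixels.
#' @param scale Integer scale factor relating the pair.
#' @param seed Integer seed.
#' @return List of `list(lr, hr)` patch pairs.
#' @export
samplePatches <- function(lr, hr, n, patch, scale, seed) {
  lr <- asImage(lr, check = FALSE); hr <- asImage(hr, check = FALSE)
  dl <- dim(lr)
  if (dl[1] < patch || dl[2] < patch)
    stop("image smaller than patch size", call. = FALSE)
  withLocalSeed(seed, {
    lapply(seq_len(n), function(i) {
      r0 <- sample.int(dl[1] - patch + 1L, 1L)
      c0 <- sample.int(dl[2] - patch + 1L, 1L)
      list(lr = lr[r0:(r0 + patch - 1L), c0:(c0 + patch - 1L), , drop = FALSE],
           hr = hr[(scale * (r0 - 1L) + 1L):(scale * (r0 + patch - 1L)),
                   (scale * (c0 - 1L) + 1L):(scale * (c0 + patch - 1L)), ,
                   drop = FALSE])
    })
  })
}

#' Degradation curriculum stage
#'
#' Two-phase progressive curriculum. Before `curriculumSwitch * epochs`,
#' LR synthesis uses the base pipeline only (bicubic downsample + blur
#' sd 1.0). From the switch point on, the stage additionally offers a menu
#' of harder degradations (blur up to sd 1.2, noise up to sd 25, JPEG
#' quality down to 20) drawn per sample with seeded probabilities during
#' training.
#'
#' @param epoch 0-based epoch index, `< epochs`.
#' @param cfg A [TrainConfig-class].
#' @param scale SR factor of the synthesis.
#' @return List of [DegradationSpec-class]: the base spec first, menu specs
#'   after the switch point.
#' @export
curriculumStage <- function(epoch, cfg, scale = 2L) {
  if (epoch >= cfg@epochs) stop("epoch must be < epochs", call. = FALSE)
  base <- degradationSpec("combined", subSpecs = list(
    degradationSpec("bicubic_down", scale = scale),
    degradationSpec("gaussian_blur", sigma = 1.0)))
  if (epoch < cfg@curriculumSwitch * cfg@epochs) return(list(base))
  list(base,
       degradationSpec("gaussian_blur", sigma = 1.2),
       degradationSpec("gaussian_noise", sigma = 25),
       degradationSpec("jpeg", quality = 20L))
}

## Resolve the HR array of a dataset item.
.hrArray <- function(item) {
  if (is(item$hr, "SyntheticFundus")) item$hr@image else asImage(item$hr, check = FALSE)
}

## Synthesise an LR patch from an HR patch under the current stage.
.stageLR <- function(hrPatch, scale, stage) {
  lr <- applyDegradation(hrPatch, stage[[1L]])
  if (length(stage) > 1L && stats::runif(1) < 0.5) {
    pick <- sample(2:length(stage), 1L)
    sp <- stage[[pick]]
    if (sp@kind == "gaussian_blur") sp@sigma <- stats::runif(1, 0.2, sp@sigma)
    if (sp@kind == "gaussian_noise") {
      sp@sigma <- stats::runif(1, 5, sp@sigma)
      sp@seed <- sample.int(2147483646L, 1L)
    }
    if (sp@kind == "jpeg") sp@quality <- sample(sp@quality:80L, 1L)
    lr <- applyDegradation(lr, sp)
  }
  asImage(lr, check = FALSE)
}

## Validation metrics over the val split.
.validate <- function(cfg, params, items, wantSsim, wantDdf) {
  ps <- c(); ss <- c(); dd <- c()
  for (it in items) {
    hr <- .hrArray(it)
    sr <- clip01(.forwardInternal(cfg, params, it$lr, keepCache = FALSE)$sr)
    ps <- c(ps, psnr(sr, hr))
    if (wantSsim) ss <- c(ss, ssim(sr, hr))
    if (wantDdf) dd <- c(dd, suppressWarnings(
      tryCatch(deltaDf(hr, sr), error = function(e) NA_real_)))
  }
  c(psnr = mean(ps),
    ssim = if (wantSsim) mean(ss) else NA_real_,
    ddf = if (wantDdf) mean(dd, na.rm = TRUE) else NA_real_)
}

#' Train a super-resolution model
#'
#' Seeded end-to-end Adam optimisation of the composite loss on randomly
#' cropped, augmented patch pairs, with the cosine learning-rate schedule
#' and the progressive degradation curriculum. Per-epoch validation PSNR
#' (and optionally SSIM / fractal-dimension difference) is recorded; best-
#' and last-epoch checkpoints are written when `checkpointDir` is given, and
#' a run can be resumed bit-identically from the last checkpoint.
#'
#' @param model An [SRModel-class] (fresh or checkpoint-loaded).
#' @param data Dataset from [makeDataset()] (or a list of items with `hr`,
#'   `lr`, `split`).
#' @param tcfg A [TrainConfig-class].
#' @param checkpointDir Optional directory for `best.rds` / `last.rds`.
#' @param resumeFrom Optional path to a `last.rds` checkpoint of the same
#'   run; training continues with identical RNG and optimiser state.
#' @param logFile Optional JSON-lines file receiving one record per epoch.
#' @param maxEpochs Run at most this many epochs in this invocation (the
#'   schedule still spans `tcfg@epochs`); used to interrupt and later resume.
#' @param verbose Print per-epoch progress.
#' @return List `(model, history)` with the trained [SRModel-class] and a
#'   [TrainHistory-class].
#' @export
trainModel <- function(model, data, tcfg, checkpointDir = NULL,
                       resumeFrom = NULL, logFile = NULL, maxEpochs = Inf,
                       verbose = FALSE) {
  validObject(tcfg)
  cfg <- model@config
  scale <- cfg@scale
  trainItems <- Filter(function(it) identical(it$split, "train"), data)
  valItems <- Filter(function(it) identical(it$split, "val"), data)
  if (!length(trainItems) || !length(valItems))
    stop("need non-empty train and validation splits", call. = FALSE)
  params <- model@params
  pspec <- perceptualSpec(seed = tcfg@seed, inChannels = cfg@inChannels)
  mAdam <- vAdam <- lapply(params, function(p) p * 0)
  stepCount <- 0L
  startEpoch <- 0L
  records <- list()
  oldSeed <- NULL
  if (!is.null(resumeFrom)) {
    ck <- readRDS(resumeFrom)
    if (!identical(ck$config, cfgAsList(cfg)))
      stop("resume checkpoint configuration mismatch", call. = FALSE)
    params <- ck$params
    mAdam <- ck$opt$m; vAdam <- ck$opt$v; stepCount <- ck$opt$step
    startEpoch <- ck$meta$epoch
    records <- ck$historySoFar
    assign(".Random.seed", ck$rngState, envir = globalenv())
  } else {
    set.seed(tcfg@seed)
  }
  b1 <- tcfg@beta1; b2 <- tcfg@beta2; eps <- tcfg@adamEps
  bestPsnr <- -Inf
  if (length(records)) {
    prior <- vapply(records, function(r) r$valPsnr, numeric(1))
    bestPsnr <- max(prior, na.rm = TRUE)
  }
  endEpoch <- min(tcfg@epochs, startEpoch + maxEpochs)
  for (epoch in (startEpoch + 1L):endEpoch) {
    lrRate <- cosineLR(epoch - 1L, tcfg)
    stage <- curriculumStage(epoch - 1L, tcfg, scale)
    lossAcc <- c(total = 0, mse = 0, perceptual = 0, fractal = 0)
    for (step in seq_len(tcfg@stepsPerEpoch)) {
      gacc <- new.env(parent = emptyenv())
      batchLoss <- c(total = 0, mse = 0, perceptual = 0, fractal = 0)
      for (bi in seq_len(tcfg@batch)) {
        it <- trainItems[[sample.int(length(trainItems), 1L)]]
        hrImg <- .hrArray(it)
        dH <- dim(hrImg)
        hp <- tcfg@patch * scale
        r0 <- sample.int(dH[1] - hp + 1L, 1L)
        c0 <- sample.int(dH[2] - hp + 1L, 1L)
        hrP <- hrImg[r0:(r0 + hp - 1L), c0:(c0 + hp - 1L), , drop = FALSE]
        lrP <- .stageLR(hrP, scale, stage)
        aug <- augmentPair(lrP, hrP, seed = sample.int(2147483646L, 1L),
                           flips = tcfg@augmentFlips, rotate = tcfg@augmentRotate,
                           jitter = tcfg@augmentJitter)
        fw <- .forwardInternal(cfg, params, aug$lr, keepCache = TRUE)
        tl <- totalLoss(fw$sr, aug$hr, tcfg@lossWeights, pspec, withGrad = TRUE)
        if (!is.finite(tl$total)) {
          badc <- names(which(!is.finite(tl$components)))
          stop("non-finite training loss (component: ",
               paste(if (length(badc)) badc else "total", collapse = ","),
               ") at epoch ", epoch, call. = FALSE)
        }
        .backwardInternal(cfg, params, fw$cache, tl$grad / tcfg@batch, gacc)
        batchLoss <- batchLoss +
          c(tl$total, tl$components) / tcfg@batch
      }
      if (tcfg@gradClip > 0) {
        nrm <- sqrt(sum(vapply(ls(gacc), function(n) sum(gacc[[n]]^2), numeric(1))))
        if (nrm > tcfg@gradClip)
          for (n in ls(gacc)) gacc[[n]] <- gacc[[n]] * (tcfg@gradClip / nrm)
      }
      stepCount <- stepCount + 1L
      corr1 <- 1 - b1^stepCount
      corr2 <- 1 - b2^stepCount
      for (n in ls(gacc)) {
        g <- gacc[[n]]
        mAdam[[n]] <- b1 * mAdam[[n]] + (1 - b1) * g
        vAdam[[n]] <- b2 * vAdam[[n]] + (1 - b2) * g^2
        params[[n]] <- params[[n]] -
          lrRate * (mAdam[[n]] / corr1) / (sqrt(vAdam[[n]] / corr2) + eps)
      }
      lossAcc <- lossAcc + batchLoss / tcfg@stepsPerEpoch
    }
    vm <- .validate(cfg, params, valItems, wantSsim = TRUE,
                    wantDdf = tcfg@valDeltaDf)
    rec <- list(epoch = epoch, lr = lrRate, loss = lossAcc[["total"]],
                lossMse = lossAcc[["mse"]],
                lossPerceptual = lossAcc[["perceptual"]],
                lossFractal = lossAcc[["fractal"]],
                valPsnr = vm[["psnr"]], valSsim = vm[["ssim"]],
                valDeltaDf = vm[["ddf"]])
    records[[length(records) + 1L]] <- rec
    if (verbose)
      message(sprintf("epoch %d/%d  lr %.2e  loss %.5f  val PSNR %.2f dB",
                      epoch, tcfg@epochs, lrRate, rec$loss, rec$valPsnr))
    if (!is.null(logFile))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = logFile, append = TRUE, sep = "")
    if (!is.null(checkpointDir)) {
      dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
      ckobj <- list(format_version = 1L, config = cfgAsList(cfg),
                    params = params,
                    meta = list(version = 1L, epoch = epoch,
                                trainSeed = tcfg@seed),
                    opt = list(m = mAdam, v = vAdam, step = stepCount),
                    rngState = get(".Random.seed", envir = globalenv()),
                    historySoFar = records)
      saveRDS(ckobj, file.path(checkpointDir, "last.rds"))
      if (is.finite(rec$valPsnr) && rec$valPsnr > bestPsnr) {
        bestPsnr <- rec$valPsnr
        saveRDS(ckobj, file.path(checkpointDir, "best.rds"))
      }
    }
  }
  hist <- new("TrainHistory",
              records = do.call(rbind, lapply(records, as.data.frame)))
  out <- new("SRModel", config = cfg, params = params,
             meta = list(version = 1L, epoch = endEpoch,
                         trainSeed = tcfg@seed, initSeed = model@meta$initSeed))
  list(model = out, history = hist)
}
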