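## The composite training objective: pixel MSE, a perceptual feature
## distance through a pluggable extractor, and the fractal-dimension term.
## Box counting is not differentiable, so the training-mode fractal loss
## uses a soft surrogate: a sigmoid vessel-probability map, per-box
## noisy-OR soft occupancy, and a closed-form least-squares slope over
## log soft counts — fully differentiable in the network output. The hard
## (evaluation) mode runs the ordinary extraction + box-counting pipeline.

#' Mean squared error loss
#'
#' @param sr,hr Images of identical shape.
#' @return Mean of squared differences over all pixels and channels.
#' @export
mseLoss <- function(sr, hr) {
  sr <- asImage(sr, check = FALSE); hr <- asImage(hr, check = FALSE)
  if (!identical(dim(sr), dim(hr))) stop("shape mismatch", call. = FALSE)
  mean((sr - hr)^2)
}

#' Perceptual feature-distance specification
#'
#' The perceptual loss compares feature maps from a fixed, deterministic
#' extractor. Kinds: `"randomconv"` (default) — a seeded random-weight
#' two-layer 3x3 convolutional extractor, self-contained and download-free;
#' `"identity"` — features are the pixels themselves, collapsing the loss to
#' MSE; `"custom"` — caller supplies `forward(img) -> feature matrix` and
#' `backward(dFeat, img) -> gradient array` (the hook through which a
#' pretrained backbone such as VGG can be plugged in).
#'
#' @param kind Extractor kind.
#' @param seed Weight seed for `"randomconv"`.
#' @param channels Feature channels of the random extractor.
#' @param inChannels Image channels the extractor expects.
#' @param forward,backward Functions for `"custom"`.
#' @return A `perceptualSpec` list object.
#' @export
perceptualSpec <- function(kind = c("randomconv", "identity", "custom"),
                           seed = 0L, channels = 8L, inChannels = 3L,
                           forward = NULL, backward = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, seed = as.integer(seed),
               channels = as.integer(channels),
               inChannels = as.integer(inChannels),
               forward = forward, backward = backward)
  if (kind == "randomconv") {
    spec$W1 <- withLocalSeed(seed, .kaiming(9L * inChannels, channels, 9L * inChannels))
    spec$W2 <- withLocalSeed(seed + 1L, .kaiming(9L * channels, channels, 9L * channels))
  }
  class(spec) <- "perceptualSpec"
  spec
}

## forward pass of the random-conv extractor; returns features + cache
.percepFwd <- function(img, spec) {
  d <- dim(img)
  ctx <- convCtx(d[1], d[2], 3L, "zero")
  c1 <- conv2dForward(img2feat(img), spec$W1, numeric(spec$channels), ctx)
  R <- reluFwd(c1$Y)
  c2 <- conv2dForward(R, spec$W2, numeric(spec$channels), ctx)
  list(F = c2$Y, pre = c1$Y, R = R, ctx = ctx)
}

#' Perceptual loss
#'
#' Mean squared feature difference, normalised by the feature-map size.
#'
#' @param sr,hr Images of identical shape.
#' @param spec A [perceptualSpec()].
#' @return Non-negative scalar.
#' @export
perceptualLoss <- function(sr, hr, spec = perceptualSpec()) {
  sr <- asImage(sr, check = FALSE); hr <- asImage(hr, check = FALSE)
  if (!identical(dim(sr), dim(hr))) stop("shape mismatch", call. = FALSE)
  switch(spec$kind,
    identity = mseLoss(sr, hr),
    randomconv = {
      fs <- .percepFwd(sr, spec)$F
      fh <- .percepFwd(hr, spec)$F
      mean((fs - fh)^2)
    },
    custom = {
      fs <- tryCatch(spec$forward(sr), error = function(e)
        stop("perceptual extractor failed (custom): ", conditionMessage(e),
             call. = FALSE))
      fh <- spec$forward(hr)
      mean((fs - fh)^2)
    })
}

## gradient of perceptualLoss w.r.t. sr (array of sr shape)
.percepGrad <- function(sr, hr, spec) {
  d <- dim(sr)
  switch(spec$kind,
    identity = 2 * (sr - hr) / length(sr),
    randomconv = {
      fs <- .percepFwd(sr, spec)
      fh <- .percepFwd(hr, spec)
      dF <- 2 * (fs$F - fh$F) / length(fs$F)
      b2 <- conv2dBackward(dF, spec$W2, fs$R, fs$ctx, spec$channels)
      dR <- reluBwd(b2$dX, fs$pre)
      b1 <- conv2dBackward(dR, spec$W1, NULL, fs$ctx, d[3])
      array(b1$dX, d)
    },
    custom = {
      fs <- spec$forward(sr); fh <- spec$forward(hr)
      spec$backward(2 * (fs - fh) / length(fs), sr)
    })
}

## ---- soft (differentiable) fractal dimension ------------------------------

## Dense 1-D reflect-padded box-mean operator (n x n), cached.  Matches
## boxMeanMatrix / the extractor's local mean exactly, and its adjoint is
## the plain transpose — so the surrogate gradient is exact at the borders.
.boxMean1dOp <- function(n, window) {
  key <- paste("bm1d", n, window, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  rad <- (window - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- reflectCoord((i - rad):(i + rad), n)
    for (j in js) M[i, j] <- M[i, j] + 1 / window
  }
  .fsr_cache[[key]] <- M
  M
}

## Soft vessel probability: sigmoid of the contrast-normalised inverted
## green channel; c = localmean(g) - g is positive where vessels (dark
## structures) sit below their neighbourhood.  The local mean is the same
## reflect-padded window-25 box mean the hard extractor thresholds, so the
## tau -> 0 limit of the soft map is the extractor's (pre-morphology) mask.
.softVesselMap <- function(img, tau = 0.05, t0 = 0.02, window = 25L) {
  g <- greenChannel(img)
  Mh <- .boxMean1dOp(nrow(g), window)
  Mw <- .boxMean1dOp(ncol(g), window)
  cmap <- Mh %*% g %*% t(Mw) - g
  v <- 1 / (1 + exp(-(cmap - t0) / tau))
  list(v = v, g = g, cmap = cmap, window = window)
}

## Halving max-reduction to box side f (power of two); returns box maxima.
.boxMax <- function(v, f) {
  while (f > 1L) {
    nr <- nrow(v); nc <- ncol(v)
    v <- pmax(v[seq(1L, nr, 2L), , drop = FALSE], v[seq(2L, nr, 2L), , drop = FALSE])
    v <- pmax(v[, seq(1L, nc, 2L), drop = FALSE], v[, seq(2L, nc, 2L), drop = FALSE])
    f <- f %/% 2L
  }
  v
}

.boxSum <- function(v, f) {
  while (f > 1L) {
    nr <- nrow(v); nc <- ncol(v)
    v <- v[seq(1L, nr, 2L), , drop = FALSE] + v[seq(2L, nr, 2L), , drop = FALSE]
    v <- v[, seq(1L, nc, 2L), drop = FALSE] + v[, seq(2L, nc, 2L), drop = FALSE]
    f <- f %/% 2L
  }
  v
}

## Soft fractal dimension of a probability map (square-power-of-two padding
## by zeros).  Soft occupancy of a box is the noisy-OR of its pixel
## probabilities, 1 - prod(1 - v): it converges to the hard box occupancy
## for near-binary maps while spreading the gradient over every pixel of
## the box (an argmax-routed max-pool concentrates the whole gradient of a
## coarse level onto single pixels, which destabilises training).
## Returns df, per-level soft counts, and what backward needs.
.softDf <- function(v) {
  h <- nrow(v); w <- ncol(v)
  maxBox <- 2L^floor(log2(min(h, w) / 4))
  if (maxBox < 4L) return(NULL)            # fewer than 3 levels
  sizes <- 2L^(0:as.integer(log2(maxBox)))
  hP <- ceiling(h / maxBox) * maxBox
  wP <- ceiling(w / maxBox) * maxBox
  vp <- matrix(0, hP, wP)
  vp[seq_len(h), seq_len(w)] <- pmin(v, 1 - 1e-6)
  lq <- log1p(-vp)                         # log(1 - v)
  delta <- 1e-8
  N <- numeric(length(sizes))
  S <- vector("list", length(sizes))       # per-box sum of log(1 - v)
  for (i in seq_along(sizes)) {
    S[[i]] <- .boxSum(lq, sizes[i])
    N[i] <- sum(1 - exp(S[[i]]))
  }
  x <- log(1 / sizes)
  xc <- x - mean(x)
  wts <- xc / sum(xc^2)                    # closed-form least-squares slope
  y <- log(N + delta)
  list(df = sum(wts * y), N = N, S = S, sizes = sizes, wts = wts,
       delta = delta, vp = vp, h = h, w = w)
}

## Gradient of .softDf$df w.r.t. the (unpadded) probability map.
## d occ / d v_j = prod_{i != j} (1 - v_i) = exp(S_box - log(1 - v_j)).
.softDfGrad <- function(sd) {
  dvp <- matrix(0, nrow(sd$vp), ncol(sd$vp))
  for (i in seq_along(sd$sizes)) {
    f <- sd$sizes[i]
    dN <- sd$wts[i] / (sd$N[i] + sd$delta)
    Sfull <- sd$S[[i]][rep(seq_len(nrow(sd$S[[i]])), each = f),
                       rep(seq_len(ncol(sd$S[[i]])), each = f), drop = FALSE]
    dvp <- dvp + dN * exp(Sfull - log1p(-sd$vp))
  }
  dvp[seq_len(sd$h), seq_len(sd$w), drop = FALSE]
}

#' Fractal-dimension loss
#'
#' `|Df(hr) - Df(sr)|`. Hard mode computes both dimensions through vessel
#' extraction and box counting (non-differentiable; evaluation and logging).
#' Soft mode computes both through the differentiable surrogate: sigmoid
#' vessel probabilities (temperature `tau`), per-box soft occupancy by
#' the noisy-OR of its pixels, and a closed-form least-squares slope of the log soft
#' counts. As `tau` shrinks on near-binary inputs the surrogate converges
#' to the hard box-counting dimension.
#'
#' @param sr,hr Images of identical shape.
#' @param mode `"soft"` (training) or `"hard"` (evaluation).
#' @param tau Soft-mode sigmoid temperature.
#' @param ... Hard mode: forwarded to [fractalDimension()].
#' @return Non-negative scalar. Soft mode on images smaller than 32 px (or
#'   entirely flat) returns 0 with a warning (the term is skipped).
#' @export
fractalLoss <- function(sr, hr, mode = c("soft", "hard"), tau = 0.05, ...) {
  mode <- match.arg(mode)
  sr <- asImage(sr, check = FALSE); hr <- asImage(hr, check = FALSE)
  if (!identical(dim(sr), dim(hr))) stop("shape mismatch", call. = FALSE)
  if (mode == "hard") return(deltaDf(hr, sr, ...))
  vs <- .softVesselMap(sr, tau)
  vh <- .softVesselMap(hr, tau)
  if (max(vh$cmap) - min(vh$cmap) < 1e-12 && max(vs$cmap) - min(vs$cmap) < 1e-12) {
    warning("flat images: soft fractal loss skipped (0)")
    return(0)
  }
  ss <- .softDf(vs$v); sh <- .softDf(vh$v)
  if (is.null(ss) || is.null(sh)) {
    warning("patch too small for 3 box levels: soft fractal loss skipped (0)")
    return(0)
  }
  abs(ss$df - sh$df)
}

## gradient of soft fractalLoss w.r.t. sr
.fractalGrad <- function(sr, hr, tau = 0.05) {
  d <- dim(sr)
  vs <- .softVesselMap(sr, tau)
  vh <- .softVesselMap(hr, tau)
  ss <- .softDf(vs$v); sh <- .softDf(vh$v)
  out <- array(0, d)
  if (is.null(ss) || is.null(sh)) return(out)
  sgn <- sign(ss$df - sh$df)
  if (sgn == 0) return(out)
  dv <- sgn * .softDfGrad(ss)
  dc <- dv * vs$v * (1 - vs$v) / tau
  ## c = M g M' - g  =>  dg = M' dc M - dc
  Mh <- .boxMean1dOp(nrow(dc), 25L)
  Mw <- .boxMean1dOp(ncol(dc), 25L)
  dg <- t(Mh) %*% dc %*% Mw - dc
  if (d[3] == 1L) out[, , 1L] <- dg else out[, , 2L] <- dg
  out
}

#' Composite training loss
#'
#' `total = w1 * MSE + w2 * perceptual + w3 * fractal`, returning the
#' components alongside the total. With `withGrad = TRUE` the gradient with
#' respect to `sr` (soft fractal mode) is attached.
#'
#' @param sr,hr Images of identical shape (raw, unclipped network output).
#' @param weights Numeric `c(mse, perceptual, fractal)` (defaults 1, 0.1, 0.05).
#' @param pspec A [perceptualSpec()] (ignored when `weights[2] == 0`).
#' @param tau Soft fractal temperature.
#' @param withGrad Also return `grad`, an array like `sr`.
#' @return List with `total`, `components` (named numeric), and optionally
#'   `grad`.
#' @export
totalLoss <- function(sr, hr, weights = c(1, 0.1, 0.05),
                      pspec = perceptualSpec(), tau = 0.05, withGrad = FALSE) {
  if (length(weights) != 3L || any(weights < 0))
    stop("weights must be 3 non-negative numbers", call. = FALSE)
  sr <- asImage(sr, check = FALSE); hr <- asImage(hr, check = FALSE)
  cMse <- mseLoss(sr, hr)
  cPer <- if (weights[2] > 0) perceptualLoss(sr, hr, pspec) else 0
  cFra <- if (weights[3] > 0)
    suppressWarnings(fractalLoss(sr, hr, "soft", tau)) else 0
  out <- list(total = weights[1] * cMse + weights[2] * cPer + weights[3] * cFra,
              components = c(mse = cMse, perceptual = cPer, fractal = cFra))
  if (withGrad) {
    g <- weights[1] * 2 * (sr - hr) / length(sr)
    if (weights[2] > 0) g <- g + weights[2] * .percepGrad(sr, hr, pspec)
    if (weights[3] > 0) g <- g + weights[3] * .fractalGrad(sr, hr, tau)
    out$grad <- g
  }
  out
}
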