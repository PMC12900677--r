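## The dual-path super-resolution network: shallow 3x3 feature extraction,
## a transformer path of residual shifted-window attention blocks, a CNN
## path of residual channel-attention blocks, pooled multi-scale fusion,
## and sub-pixel reconstruction over a bicubic global residual.

.tn <- function(n, m, sd = 0.02) {
  ## truncated normal (clipped at 2 sd), the standard transformer init
  matrix(pmin(pmax(stats::rnorm(n * m, 0, sd), -2 * sd), 2 * sd), n, m)
}

.kaiming <- function(n, m, fan_in) matrix(stats::rnorm(n * m, 0, sqrt(2 / fan_in)), n, m)

#' Initialise the network parameters
#'
#' Truncated normal (sd 0.02) for attention, MLP, fusion and
#' channel-attention weights; Kaiming-normal for 3x3 convolutions; zeros for
#' every bias, the relative-position bias tables, and the final
#' reconstruction convolution — so a freshly initialised model reproduces
#' the bicubic baseline exactly.
#'
#' @param cfg A [ModelConfig-class].
#' @param seed Integer seed.
#' @return Named list of weight arrays.
#' @export
initParameters <- function(cfg, seed = 0L) {
  validObject(cfg)
  d <- cfg@featureDim
  m <- as.integer(round(cfg@mlpRatio * d))
  dr <- d %/% cfg@caReduction
  nb <- (2L * cfg@window - 1L)^2
  Cin <- cfg@inChannels
  withLocalSeed(seed, {
    p <- list()
    p[["shallow.W"]] <- .kaiming(9L * Cin, d, 9L * Cin)
    p[["shallow.b"]] <- numeric(d)
    for (i in seq_len(cfg@nRSTB)) {
      for (j in seq_len(cfg@stlPerRSTB)) {
        pre <- sprintf("t%d.s%d", i, j)
        p[[paste0(pre, ".ln1.g")]] <- rep(1, d)
        p[[paste0(pre, ".ln1.b")]] <- numeric(d)
        for (nm in c("Wq", "Wk", "Wv", "Wo"))
          p[[paste0(pre, ".attn.", nm)]] <- .tn(d, d)
        for (nm in c("bq", "bk", "bv", "bo"))
          p[[paste0(pre, ".attn.", nm)]] <- numeric(d)
        p[[paste0(pre, ".attn.relbias")]] <- matrix(0, nb, cfg@heads)
        p[[paste0(pre, ".ln2.g")]] <- rep(1, d)
        p[[paste0(pre, ".ln2.b")]] <- numeric(d)
        p[[paste0(pre, ".mlp.W1")]] <- .tn(d, m)
        p[[paste0(pre, ".mlp.b1")]] <- numeric(m)
        p[[paste0(pre, ".mlp.W2")]] <- .tn(m, d)
        p[[paste0(pre, ".mlp.b2")]] <- numeric(d)
      }
      p[[sprintf("t%d.conv.W", i)]] <- .kaiming(9L * d, d, 9L * d)
      p[[sprintf("t%d.conv.b", i)]] <- numeric(d)
    }
    for (i in seq_len(cfg@nRCAB)) {
      p[[sprintf("c%d.conv1.W", i)]] <- .kaiming(9L * d, d, 9L * d)
      p[[sprintf("c%d.conv1.b", i)]] <- numeric(d)
      p[[sprintf("c%d.conv2.W", i)]] <- .kaiming(9L * d, d, 9L * d)
      p[[sprintf("c%d.conv2.b", i)]] <- numeric(d)
      p[[sprintf("c%d.ca.W1", i)]] <- .tn(d, dr)
      ## small positive bias keeps every bottleneck unit active at init
      p[[sprintf("c%d.ca.b1", i)]] <- rep(0.01, dr)
      p[[sprintf("c%d.ca.W2", i)]] <- .tn(dr, d)
      p[[sprintf("c%d.ca.b2", i)]] <- numeric(d)
    }
    nPaths <- (cfg@nRSTB > 0L) + (cfg@nRCAB > 0L)
    for (l in seq_len(cfg@fusionScales)) {
      p[[sprintf("fuse.s%d.W", l)]] <- .tn(nPaths * d, d)
      p[[sprintf("fuse.s%d.b", l)]] <- numeric(d)
    }
    for (k in seq_len(as.integer(log2(cfg@scale)))) {
      p[[sprintf("up.s%d.W", k)]] <- .kaiming(9L * d, 4L * d, 9L * d)
      p[[sprintf("up.s%d.b", k)]] <- numeric(4L * d)
    }
    p[["up.final.W"]] <- matrix(0, 9L * d, Cin)   # zero: start at bicubic
    p[["up.final.b"]] <- numeric(Cin)
    p
  })
}

#' Exact learnable parameter count of a configuration
#'
#' Closed-form count from the configuration alone; equals the total number
#' of scalars produced by [initParameters()].
#'
#' @param cfg A [ModelConfig-class].
#' @param breakdown Return a per-component named vector instead of the total.
#' @return Integer count (or named numeric vector).
#' @export
countParameters <- function(cfg, breakdown = FALSE) {
  d <- cfg@featureDim
  m <- as.integer(round(cfg@mlpRatio * d))
  dr <- d %/% cfg@caReduction
  nb <- (2L * cfg@window - 1L)^2
  Cin <- cfg@inChannels
  stl <- 2 * d + 4 * (d^2 + d) + nb * cfg@heads + 2 * d +
    (d * m + m) + (m * d + d)
  comp <- c(
    shallow = 9 * Cin * d + d,
    transformer = cfg@nRSTB * (cfg@stlPerRSTB * stl + 9 * d^2 + d),
    cnn = cfg@nRCAB * (2 * (9 * d^2 + d) + d * dr + dr + dr * d + d),
    fusion = cfg@fusionScales *
      (((cfg@nRSTB > 0) + (cfg@nRCAB > 0)) * d^2 + d),
    upsampler = log2(cfg@scale) * (9 * d * 4 * d + 4 * d) + 9 * d * Cin + Cin)
  if (breakdown) comp else as.integer(sum(comp))
}

#' Construct a model with freshly initialised weights
#'
#' @param cfg A [ModelConfig-class] (default [tinyModelConfig()]).
#' @param seed Integer init seed.
#' @return An [SRModel-class].
#' @export
srModel <- function(cfg = tinyModelConfig(), seed = 0L) {
  new("SRModel", config = cfg, params = initParameters(cfg, seed),
      meta = list(version = 1L, initSeed = as.integer(seed), epoch = 0L))
}

## ---- forward -------------------------------------------------------------

.stlForward <- function(X, p, pre, wctx, heads) {
  ln1 <- lnFwd(X, p[[paste0(pre, ".ln1.g")]], p[[paste0(pre, ".ln1.b")]])
  at <- attnFwd(ln1$Y, list(
    Wq = p[[paste0(pre, ".attn.Wq")]], Wk = p[[paste0(pre, ".attn.Wk")]],
    Wv = p[[paste0(pre, ".attn.Wv")]], Wo = p[[paste0(pre, ".attn.Wo")]],
    bq = p[[paste0(pre, ".attn.bq")]], bk = p[[paste0(pre, ".attn.bk")]],
    bv = p[[paste0(pre, ".attn.bv")]], bo = p[[paste0(pre, ".attn.bo")]],
    relbias = p[[paste0(pre, ".attn.relbias")]]), wctx, heads)
  X1 <- X + at$Y
  ln2 <- lnFwd(X1, p[[paste0(pre, ".ln2.g")]], p[[paste0(pre, ".ln2.b")]])
  M1 <- denseFwd(ln2$Y, p[[paste0(pre, ".mlp.W1")]], p[[paste0(pre, ".mlp.b1")]])
  G <- geluFwd(M1)
  M2 <- denseFwd(G, p[[paste0(pre, ".mlp.W2")]], p[[paste0(pre, ".mlp.b2")]])
  list(Y = X1 + M2, ln1 = ln1, at = at, X1 = X1, ln2 = ln2, M1 = M1, G = G)
}

.stlBackward <- function(dY, cache, p, pre, wctx, heads, gacc) {
  dX1 <- dY
  b2 <- denseBwd(dY, cache$G, p[[paste0(pre, ".mlp.W2")]])
  addGrad(gacc, paste0(pre, ".mlp.W2"), b2$dW)
  addGrad(gacc, paste0(pre, ".mlp.b2"), b2$db)
  dM1 <- geluBwd(b2$dX, cache$M1)
  b1 <- denseBwd(dM1, cache$ln2$Y, p[[paste0(pre, ".mlp.W1")]])
  addGrad(gacc, paste0(pre, ".mlp.W1"), b1$dW)
  addGrad(gacc, paste0(pre, ".mlp.b1"), b1$db)
  l2 <- lnBwd(b1$dX, cache$ln2, p[[paste0(pre, ".ln2.g")]])
  addGrad(gacc, paste0(pre, ".ln2.g"), l2$dg)
  addGrad(gacc, paste0(pre, ".ln2.b"), l2$db)
  dX1 <- dX1 + l2$dX
  dX <- dX1
  dAttnY <- attnBwd(dX1, cache$at, list(
    Wq = p[[paste0(pre, ".attn.Wq")]], Wk = p[[paste0(pre, ".attn.Wk")]],
    Wv = p[[paste0(pre, ".attn.Wv")]], Wo = p[[paste0(pre, ".attn.Wo")]]),
    wctx, heads, gacc, paste0(pre, ".attn"))
  l1 <- lnBwd(dAttnY, cache$ln1, p[[paste0(pre, ".ln1.g")]])
  addGrad(gacc, paste0(pre, ".ln1.g"), l1$dg)
  addGrad(gacc, paste0(pre, ".ln1.b"), l1$db)
  dX + l1$dX
}

.caForward <- function(F2, p, pre) {
  gap <- matrix(colMeans(F2), 1L)
  z1 <- denseFwd(gap, p[[paste0(pre, ".W1")]], p[[paste0(pre, ".b1")]])
  r1 <- reluFwd(z1)
  z2 <- denseFwd(r1, p[[paste0(pre, ".W2")]], p[[paste0(pre, ".b2")]])
  a <- sigmoidFwd(z2)
  Y <- sweep(F2, 2L, a[1L, ], `*`)
  list(Y = Y, gap = gap, z1 = z1, r1 = r1, a = a, F2 = F2)
}

.caBackward <- function(dY, cache, p, pre, gacc) {
  a <- cache$a[1L, ]
  dF2 <- sweep(dY, 2L, a, `*`)
  da <- matrix(colSums(dY * cache$F2), 1L)
  dz2 <- da * cache$a * (1 - cache$a)
  b2 <- denseBwd(dz2, cache$r1, p[[paste0(pre, ".W2")]])
  addGrad(gacc, paste0(pre, ".W2"), b2$dW)
  addGrad(gacc, paste0(pre, ".b2"), b2$db)
  dr1 <- reluBwd(b2$dX, cache$z1)
  b1 <- denseBwd(dr1, cache$gap, p[[paste0(pre, ".W1")]])
  addGrad(gacc, paste0(pre, ".W1"), b1$dW)
  addGrad(gacc, paste0(pre, ".b1"), b1$db)
  hw <- nrow(cache$F2)
  dF2 + matrix(b1$dX[1L, ] / hw, hw, ncol(dF2), byrow = TRUE)
}

## Full forward pass on the feature-matrix representation.
## Returns list(sr = HxWxC array, unclipped; cache for the backward pass).
.forwardInternal <- function(cfg, p, lr, keepCache = TRUE) {
  lr <- asImage(lr, check = FALSE)
  h <- dim(lr)[1]; w <- dim(lr)[2]
  d <- cfg@featureDim
  X0 <- img2feat(lr)
  ctxS <- convCtx(h, w, 3L, "reflect")   # shallow layer: reflective padding
  ctx3 <- convCtx(h, w, 3L, "zero")      # interior convolutions: zero padding
  sh <- conv2dForward(X0, p[["shallow.W"]], p[["shallow.b"]], ctxS)
  F0 <- sh$Y
  ## transformer path
  Ft <- F0
  tc <- vector("list", cfg@nRSTB)
  for (i in seq_len(cfg@nRSTB)) {
    Fin <- Ft
    stls <- vector("list", cfg@stlPerRSTB)
    for (j in seq_len(cfg@stlPerRSTB)) {
      shift <- if (j %% 2L == 0L) cfg@window %/% 2L else 0L
      wctx <- windowCtx(h, w, cfg@window, shift)
      s <- .stlForward(Ft, p, sprintf("t%d.s%d", i, j), wctx, cfg@heads)
      stls[[j]] <- s
      Ft <- s$Y
    }
    cv <- conv2dForward(Ft, p[[sprintf("t%d.conv.W", i)]],
                        p[[sprintf("t%d.conv.b", i)]], ctx3)
    tc[[i]] <- list(stls = stls, convCol = cv$Col, stlOut = Ft)
    Ft <- cv$Y + Fin
  }
  ## CNN path
  Fc <- F0
  cc <- vector("list", cfg@nRCAB)
  for (i in seq_len(cfg@nRCAB)) {
    Xin <- Fc
    c1 <- conv2dForward(Xin, p[[sprintf("c%d.conv1.W", i)]],
                        p[[sprintf("c%d.conv1.b", i)]], ctx3)
    R <- reluFwd(c1$Y)
    c2 <- conv2dForward(R, p[[sprintf("c%d.conv2.W", i)]],
                        p[[sprintf("c%d.conv2.b", i)]], ctx3)
    ca <- .caForward(c2$Y, p, sprintf("c%d.ca", i))
    cc[[i]] <- list(col1 = c1$Col, preRelu = c1$Y, R = R, col2 = c2$Col, ca = ca)
    Fc <- ca$Y + Xin
  }
  ## multi-scale fusion; a disabled path (0 blocks) contributes nothing
  Cc <- if (cfg@nRSTB == 0L) Fc else if (cfg@nRCAB == 0L) Ft else cbind(Ft, Fc)
  Ff <- matrix(0, h * w, d)
  fu <- vector("list", cfg@fusionScales)
  for (l in seq_len(cfg@fusionScales)) {
    f <- 2L^(l - 1L)
    if (f == 1L) {
      Z <- denseFwd(Cc, p[[sprintf("fuse.s%d.W", l)]], p[[sprintf("fuse.s%d.b", l)]])
      fu[[l]] <- list(f = f)
      Ff <- Ff + Z
    } else {
      pc <- poolCtx(h, w, f)
      P <- avgPoolFwd(Cc, pc)
      Z <- denseFwd(P, p[[sprintf("fuse.s%d.W", l)]], p[[sprintf("fuse.s%d.b", l)]])
      U <- bilinearUpFwd(Z, pc$hs, pc$ws, h, w)
      fu[[l]] <- list(f = f, pc = pc, P = P)
      Ff <- Ff + U
    }
  }
  ## reconstruction
  cur <- Ff; ch <- h; cw <- w
  up <- list()
  for (k in seq_len(as.integer(log2(cfg@scale)))) {
    ctxk <- convCtx(ch, cw, 3L, "zero")
    uc <- conv2dForward(cur, p[[sprintf("up.s%d.W", k)]],
                        p[[sprintf("up.s%d.b", k)]], ctxk)
    psc <- pixelShuffleCtx(ch, cw)
    up[[k]] <- list(inCol = uc$Col, preShuffle = uc$Y, ch = ch, cw = cw)
    cur <- pixelShuffleFwd(uc$Y, psc)
    ch <- 2L * ch; cw <- 2L * cw
  }
  ctxF <- convCtx(ch, cw, 3L, "zero")
  fin <- conv2dForward(cur, p[["up.final.W"]], p[["up.final.b"]], ctxF)
  base <- bicubicResize(lr, ch, cw, clip = FALSE)
  sr <- feat2img(fin$Y, ch, cw) + base
  cache <- if (keepCache)
    list(h = h, w = w, X0 = X0, shCol = sh$Col, F0 = F0, tc = tc, cc = cc,
         Ft = Ft, Fc = Fc, Cc = Cc, fu = fu, Ff = Ff, up = up,
         finCol = fin$Col, upIn = cur, outH = ch, outW = cw)
  else NULL
  list(sr = sr, cache = cache)
}

## Backward pass: dSR is the gradient of the loss w.r.t. the SR array.
## Accumulates parameter gradients (named like params) into `gacc`.
.backwardInternal <- function(cfg, p, cache, dSR, gacc) {
  d <- cfg@featureDim
  h <- cache$h; w <- cache$w
  dFin <- matrix(dSR, cache$outH * cache$outW, cfg@inChannels)
  ctxF <- convCtx(cache$outH, cache$outW, 3L, "zero")
  bf <- conv2dBackward(dFin, p[["up.final.W"]], cache$finCol, ctxF, d)
  addGrad(gacc, "up.final.W", bf$dW)
  addGrad(gacc, "up.final.b", bf$db)
  dCur <- bf$dX
  for (k in rev(seq_along(cache$up))) {
    u <- cache$up[[k]]
    psc <- pixelShuffleCtx(u$ch, u$cw)
    dPre <- pixelShuffleBwd(dCur, psc)
    ctxk <- convCtx(u$ch, u$cw, 3L, "zero")
    bu <- conv2dBackward(dPre, p[[sprintf("up.s%d.W", k)]], u$inCol, ctxk, d)
    addGrad(gacc, sprintf("up.s%d.W", k), bu$dW)
    addGrad(gacc, sprintf("up.s%d.b", k), bu$db)
    dCur <- bu$dX
  }
  dFf <- dCur
  ## fusion backward
  nPaths <- (cfg@nRSTB > 0L) + (cfg@nRCAB > 0L)
  dC <- matrix(0, h * w, nPaths * d)
  for (l in seq_along(cache$fu)) {
    fl <- cache$fu[[l]]
    if (fl$f == 1L) {
      bz <- denseBwd(dFf, cache$Cc, p[[sprintf("fuse.s%d.W", l)]])
      addGrad(gacc, sprintf("fuse.s%d.W", l), bz$dW)
      addGrad(gacc, sprintf("fuse.s%d.b", l), bz$db)
      dC <- dC + bz$dX
    } else {
      dZ <- bilinearUpBwd(dFf, fl$pc$hs, fl$pc$ws, h, w)
      bz <- denseBwd(dZ, fl$P, p[[sprintf("fuse.s%d.W", l)]])
      addGrad(gacc, sprintf("fuse.s%d.W", l), bz$dW)
      addGrad(gacc, sprintf("fuse.s%d.b", l), bz$db)
      dC <- dC + avgPoolBwd(bz$dX, fl$pc)
    }
  }
  if (cfg@nRSTB == 0L) {
    dFt <- matrix(0, h * w, d); dFc <- dC
  } else if (cfg@nRCAB == 0L) {
    dFt <- dC; dFc <- matrix(0, h * w, d)
  } else {
    dFt <- dC[, seq_len(d), drop = FALSE]
    dFc <- dC[, d + seq_len(d), drop = FALSE]
  }
  ctx3 <- convCtx(h, w, 3L, "zero")
  ## CNN path backward
  dF0 <- matrix(0, h * w, d)
  for (i in rev(seq_along(cache$cc))) {
    b <- cache$cc[[i]]
    dXin <- dFc
    dY2 <- .caBackward(dFc, b$ca, p, sprintf("c%d.ca", i), gacc)
    b2 <- conv2dBackward(dY2, p[[sprintf("c%d.conv2.W", i)]], b$col2, ctx3, d)
    addGrad(gacc, sprintf("c%d.conv2.W", i), b2$dW)
    addGrad(gacc, sprintf("c%d.conv2.b", i), b2$db)
    dR <- reluBwd(b2$dX, b$preRelu)
    b1 <- conv2dBackward(dR, p[[sprintf("c%d.conv1.W", i)]], b$col1, ctx3, d)
    addGrad(gacc, sprintf("c%d.conv1.W", i), b1$dW)
    addGrad(gacc, sprintf("c%d.conv1.b", i), b1$db)
    dFc <- dXin + b1$dX
  }
  dF0 <- dF0 + dFc
  ## transformer path backward
  for (i in rev(seq_along(cache$tc))) {
    blk <- cache$tc[[i]]
    dFin <- dFt
    bc <- conv2dBackward(dFt, p[[sprintf("t%d.conv.W", i)]], blk$convCol, ctx3, d)
    addGrad(gacc, sprintf("t%d.conv.W", i), bc$dW)
    addGrad(gacc, sprintf("t%d.conv.b", i), bc$db)
    dS <- bc$dX
    for (j in rev(seq_along(blk$stls))) {
      shift <- if (j %% 2L == 0L) cfg@window %/% 2L else 0L
      wctx <- windowCtx(h, w, cfg@window, shift)
      dS <- .stlBackward(dS, blk$stls[[j]], p, sprintf("t%d.s%d", i, j),
                         wctx, cfg@heads, gacc)
    }
    dFt <- dFin + dS
  }
  dF0 <- dF0 + dFt
  bs <- conv2dBackward(dF0, p[["shallow.W"]], cache$shCol, ctx3, cfg@inChannels)
  addGrad(gacc, "shallow.W", bs$dW)
  addGrad(gacc, "shallow.b", bs$db)
  invisible(NULL)
}

## ---- exported surface ----------------------------------------------------

#' Run the network forward
#'
#' Full composition: shallow extraction, parallel transformer and CNN paths,
#' multi-scale fusion, sub-pixel reconstruction plus the bicubic global
#' residual. Deterministic given the model and input. The output is
#' **unclipped** (training operates on the raw values); use [enhanceImage()]
#' for a `[0,1]`-clipped result.
#'
#' @param model An [SRModel-class].
#' @param lr LR image array.
#' @return SR image array of `scale` times the input size, unclipped.
#' @export
srForward <- function(model, lr) {
  .forwardInternal(model@config, model@params, lr, keepCache = FALSE)$sr
}

#' Super-resolve an image with a trained model
#'
#' [srForward()] followed by clipping to `[0, 1]`.
#'
#' @inheritParams srForward
#' @return SR image array in `[0, 1]`.
#' @export
enhanceImage <- function(model, lr) clip01(srForward(model, lr))

#' Inspect intermediate feature maps
#'
#' Exposed path-level operations for analysis and testing: shallow features,
#' the transformer path output, the CNN path output, their fusion, and the
#' reconstruction given fused features. All take and return `h x w x d`
#' arrays.
#'
#' @param model An [SRModel-class].
#' @param lr LR image array.
#' @return `shallowFeatures`: `h x w x d` array.
#' @export
shallowFeatures <- function(model, lr) {
  lr <- asImage(lr, check = FALSE)
  h <- dim(lr)[1]; w <- dim(lr)[2]
  ctx3 <- convCtx(h, w, 3L, "zero")
  F0 <- conv2dForward(img2feat(lr), model@params[["shallow.W"]],
                      model@params[["shallow.b"]], ctx3)$Y
  feat2img(F0, h, w)
}

#' @rdname shallowFeatures
#' @param f0 Feature array `h x w x d` (from [shallowFeatures()]).
#' @export
transformerFeatures <- function(model, f0) {
  cfg <- model@config; p <- model@params
  h <- dim(f0)[1]; w <- dim(f0)[2]
  Ft <- matrix(f0, h * w, dim(f0)[3])
  ctx3 <- convCtx(h, w, 3L, "zero")
  for (i in seq_len(cfg@nRSTB)) {
    Fin <- Ft
    for (j in seq_len(cfg@stlPerRSTB)) {
      shift <- if (j %% 2L == 0L) cfg@window %/% 2L else 0L
      wctx <- windowCtx(h, w, cfg@window, shift)
      Ft <- .stlForward(Ft, p, sprintf("t%d.s%d", i, j), wctx, cfg@heads)$Y
    }
    Ft <- conv2dForward(Ft, p[[sprintf("t%d.conv.W", i)]],
                        p[[sprintf("t%d.conv.b", i)]], ctx3)$Y + Fin
  }
  feat2img(Ft, h, w)
}

#' @rdname shallowFeatures
#' @export
cnnFeatures <- function(model, f0) {
  cfg <- model@config; p <- model@params
  h <- dim(f0)[1]; w <- dim(f0)[2]
  Fc <- matrix(f0, h * w, dim(f0)[3])
  ctx3 <- convCtx(h, w, 3L, "zero")
  for (i in seq_len(cfg@nRCAB)) {
    Xin <- Fc
    c1 <- conv2dForward(Xin, p[[sprintf("c%d.conv1.W", i)]],
                        p[[sprintf("c%d.conv1.b", i)]], ctx3)
    R <- reluFwd(c1$Y)
    c2 <- conv2dForward(R, p[[sprintf("c%d.conv2.W", i)]],
                        p[[sprintf("c%d.conv2.b", i)]], ctx3)
    Fc <- .caForward(c2$Y, p, sprintf("c%d.ca", i))$Y + Xin
  }
  feat2img(Fc, h, w)
}

#' @rdname shallowFeatures
#' @param ft,fc Transformer- and CNN-path feature arrays of equal shape.
#' @export
fuseFeatures <- function(model, ft, fc) {
  if (!identical(dim(ft), dim(fc))) stop("shape mismatch", call. = FALSE)
  cfg <- model@config; p <- model@params
  if (cfg@nRSTB == 0L || cfg@nRCAB == 0L)
    stop("fuseFeatures requires a dual-path configuration", call. = FALSE)
  h <- dim(ft)[1]; w <- dim(ft)[2]; d <- cfg@featureDim
  Cc <- cbind(matrix(ft, h * w, d), matrix(fc, h * w, d))
  Ff <- matrix(0, h * w, d)
  for (l in seq_len(cfg@fusionScales)) {
    f <- 2L^(l - 1L)
    if (f == 1L) {
      Ff <- Ff + denseFwd(Cc, p[[sprintf("fuse.s%d.W", l)]],
                          p[[sprintf("fuse.s%d.b", l)]])
    } else {
      pc <- poolCtx(h, w, f)
      Z <- denseFwd(avgPoolFwd(Cc, pc), p[[sprintf("fuse.s%d.W", l)]],
                    p[[sprintf("fuse.s%d.b", l)]])
      Ff <- Ff + bilinearUpFwd(Z, pc$hs, pc$ws, h, w)
    }
  }
  feat2img(Ff, h, w)
}

#' @rdname shallowFeatures
#' @param ff Fused feature array.
#' @export
reconstructSR <- function(model, ff, lr) {
  cfg <- model@config; p <- model@params
  h <- dim(ff)[1]; w <- dim(ff)[2]; d <- cfg@featureDim
  cur <- matrix(ff, h * w, d); ch <- h; cw <- w
  for (k in seq_len(as.integer(log2(cfg@scale)))) {
    uc <- conv2dForward(cur, p[[sprintf("up.s%d.W", k)]],
                        p[[sprintf("up.s%d.b", k)]], convCtx(ch, cw, 3L, "zero"))
    cur <- pixelShuffleFwd(uc$Y, pixelShuffleCtx(ch, cw))
    ch <- 2L * ch; cw <- 2L * cw
  }
  fin <- conv2dForward(cur, p[["up.final.W"]], p[["up.final.b"]],
                       convCtx(ch, cw, 3L, "zero"))
  feat2img(fin$Y, ch, cw) + bicubicResize(asImage(lr, check = FALSE), ch, cw,
                                          clip = FALSE)
}

#' Windowed multi-head self-attention on a feature array
#'
#' Applies the attention operator of the given transformer layer (default
#' the first) to a feature array, with the requested cyclic shift. Spatial
#' dimensions are padded internally to window multiples and cropped on
#' output; attention weights per query sum to one.
#'
#' @param model An [SRModel-class].
#' @param f Feature array `h x w x d`.
#' @param shift 0 or `window/2`.
#' @param block,layer Which transformer block / layer's weights to use.
#' @return Feature array of the same shape.
#' @export
windowAttention <- function(model, f, shift = 0L, block = 1L, layer = 1L) {
  cfg <- model@config; p <- model@params
  h <- dim(f)[1]; w <- dim(f)[2]
  pre <- sprintf("t%d.s%d", block, layer)
  wctx <- windowCtx(h, w, cfg@window, as.integer(shift))
  at <- attnFwd(matrix(f, h * w, dim(f)[3]), list(
    Wq = p[[paste0(pre, ".attn.Wq")]], Wk = p[[paste0(pre, ".attn.Wk")]],
    Wv = p[[paste0(pre, ".attn.Wv")]], Wo = p[[paste0(pre, ".attn.Wo")]],
    bq = p[[paste0(pre, ".attn.bq")]], bk = p[[paste0(pre, ".attn.bk")]],
    bv = p[[paste0(pre, ".attn.bv")]], bo = p[[paste0(pre, ".attn.bo")]],
    relbias = p[[paste0(pre, ".attn.relbias")]]), wctx, cfg@heads)
  feat2img(at$Y, h, w)
}

#' Channel attention gating on a feature array
#'
#' Global-average-pooled squeeze, bottleneck of reduction `r`, sigmoid gate,
#' channel-wise rescale, using the weights of CNN block `block`.
#'
#' @param model An [SRModel-class].
#' @param f Feature array `h x w x d`.
#' @param block Which CNN block's channel-attention weights to use.
#' @return Gated feature array of the same shape.
#' @export
channelAttention <- function(model, f, block = 1L) {
  h <- dim(f)[1]; w <- dim(f)[2]
  Y <- .caForward(matrix(f, h * w, dim(f)[3]), model@params,
                  sprintf("c%d.ca", block))$Y
  feat2img(Y, h, w)
}

## ---- checkpoints ---------------------------------------------------------

cfgAsList <- function(cfg) {
  list(scale = cfg@scale, feature_dim = cfg@featureDim, n_rstb = cfg@nRSTB,
       stl_per_rstb = cfg@stlPerRSTB, n_rcab = cfg@nRCAB, window = cfg@window,
       heads = cfg@heads, mlp_ratio = cfg@mlpRatio,
       ca_reduction = cfg@caReduction, fusion_scales = cfg@fusionScales,
       in_channels = cfg@inChannels)
}

cfgFromList <- function(x) {
  modelConfig(scale = x$scale, featureDim = x$feature_dim, nRSTB = x$n_rstb,
              stlPerRSTB = x$stl_per_rstb, nRCAB = x$n_rcab, window = x$window,
              heads = x$heads, mlpRatio = x$mlp_ratio,
              caReduction = x$ca_reduction, fusionScales = x$fusion_scales,
              inChannels = x$in_channels)
}

#' Save / load a model checkpoint
#'
#' The checkpoint archive holds a format version, the configuration, the
#' named weight arrays, and training metadata (optimiser state and RNG state
#' when saved mid-training, enabling bit-identical resumption).
#'
#' @param model An [SRModel-class].
#' @param path Checkpoint file path.
#' @param extra Named list merged into the stored metadata.
#' @export
saveCheckpoint <- function(model, path, extra = list()) {
  obj <- list(format_version = 1L, config = cfgAsList(model@config),
              params = model@params, meta = utils::modifyList(model@meta, extra))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param expectConfig Optional [ModelConfig-class]; loading a checkpoint
#'   whose configuration differs is an error, never a silent cast.
#' @return `loadCheckpoint`: an [SRModel-class] with metadata attached.
#' @export
loadCheckpoint <- function(path, expectConfig = NULL) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported checkpoint format", call. = FALSE)
  cfg <- cfgFromList(obj$config)
  if (!is.null(expectConfig) && !identical(cfgAsList(expectConfig), obj$config))
    stop("checkpoint configuration does not match the requested configuration",
         call. = FALSE)
  new("SRModel", config = cfg, params = obj$params, meta = obj$meta)
}
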