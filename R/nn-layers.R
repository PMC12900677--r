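## Differentiable layer primitives for the dual-path network. Every layer
## exposes a forward returning (output, cache) and a matching hand-derived
## backward. Feature maps are matrices of shape (h*w) x d in column-major
## position order; gradients with respect to parameters are accumulated
## into an environment keyed by parameter name.

addGrad <- function(gacc, name, g) {
  cur <- gacc[[name]]
  gacc[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

## ---- dense / pointwise ---------------------------------------------------

denseFwd <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

denseBwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

reluFwd <- function(X) pmax(X, 0)
reluBwd <- function(dY, X) dY * (X > 0)

geluFwd <- function(X) X * stats::pnorm(X)
geluBwd <- function(dY, X) dY * (stats::pnorm(X) + X * stats::dnorm(X))

sigmoidFwd <- function(X) 1 / (1 + exp(-X))

## ---- layer norm (per position over channels) ------------------------------

lnFwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(X)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, inv = inv)
}

lnBwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

## ---- window attention geometry -------------------------------------------

## Cached geometry for (h, w, win, shift): padded dims, token permutation
## grouping positions into windows, the relative-position index, and the
## per-window additive attention masks for shifted layers.
windowCtx <- function(h, w, win, shift) {
  key <- paste("win", h, w, win, shift, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- ceiling(h / win) * win
  wp <- ceiling(w / win) * win
  ## map padded positions to source positions (0 = zero pad)
  srcmap <- integer(hp * wp)
  for (c0 in seq_len(wp)) {
    for (r0 in seq_len(hp)) {
      p <- r0 + (c0 - 1L) * hp
      srcmap[p] <- if (r0 <= h && c0 <= w) r0 + (c0 - 1L) * h else 0L
    }
  }
  ## cyclic shift (roll up-left by `shift`) applied on the padded grid
  rows <- if (shift > 0) ((seq_len(hp) - 1L + shift) %% hp) + 1L else seq_len(hp)
  cols <- if (shift > 0) ((seq_len(wp) - 1L + shift) %% wp) + 1L else seq_len(wp)
  rollmap <- as.vector(outer(rows, (cols - 1L) * hp, `+`))
  ## window grouping on the (rolled) padded grid, windows row-major,
  ## tokens column-major within each window
  nwh <- hp %/% win; nww <- wp %/% win
  perm <- integer(hp * wp)
  t0 <- 1L
  winOf <- integer(hp * wp)
  for (bw in seq_len(nww)) for (bh in seq_len(nwh)) {
    rr <- (bh - 1L) * win + seq_len(win)
    cc <- (bw - 1L) * win + seq_len(win)
    tok <- as.vector(outer(rr, (cc - 1L) * hp, `+`))
    perm[t0:(t0 + win * win - 1L)] <- tok
    winOf[t0:(t0 + win * win - 1L)] <- (bw - 1L) * nwh + bh
    t0 <- t0 + win * win
  }
  ## relative position index (win^2 x win^2) for the bias table
  tr <- rep(seq_len(win), times = win)
  tc <- rep(seq_len(win), each = win)
  dr <- outer(tr, tr, `-`); dc <- outer(tc, tc, `-`)
  relidx <- (dr + win) + (2L * win - 1L) * (dc + win - 1L)
  ## attention masks for shifted windows: region labels per padded position
  masks <- NULL
  if (shift > 0) {
    sliceLab <- function(n) {
      lab <- integer(n)
      lab[seq_len(max(0L, n - win))] <- 0L
      if (n - win + 1L <= n - shift) lab[(n - win + 1L):(n - shift)] <- 1L
      lab[(n - shift + 1L):n] <- 2L
      lab
    }
    rl <- sliceLab(hp); cl <- sliceLab(wp)
    reg <- as.vector(outer(rl[rows], 3L * cl[cols], `+`))  # after roll
    nwin <- nwh * nww
    masks <- vector("list", nwin)
    for (wi in seq_len(nwin)) {
      tok <- perm[((wi - 1L) * win * win + 1L):(wi * win * win)]
      rw <- reg[tok]
      M <- outer(rw, rw, function(a, b) ifelse(a == b, 0, -1e9))
      masks[[wi]] <- M
    }
  }
  ctx <- list(h = h, w = w, win = win, shift = shift, hp = hp, wp = wp,
              srcmap = srcmap, rollmap = rollmap, perm = perm,
              nwin = (hp %/% win) * (wp %/% win), relidx = relidx,
              masks = masks)
  .fsr_cache[[key]] <- ctx
  ctx
}

## Gather X ((h*w) x d) into window-token order ((hp*wp) x d).
winGather <- function(X, ctx) {
  nz <- ctx$srcmap > 0L
  P <- matrix(0, ctx$hp * ctx$wp, ncol(X))
  P[nz, ] <- X[ctx$srcmap[nz], , drop = FALSE]
  P[ctx$rollmap, , drop = FALSE][ctx$perm, , drop = FALSE]
}

## Scatter window-token-order gradients back to (h*w) x d.
winScatter <- function(dT, ctx) {
  dRoll <- matrix(0, ctx$hp * ctx$wp, ncol(dT))
  dRoll[ctx$perm, ] <- dT
  dP <- matrix(0, ctx$hp * ctx$wp, ncol(dT))
  dP[ctx$rollmap, ] <- dRoll
  nz <- ctx$srcmap > 0L
  dX <- matrix(0, ctx$h * ctx$w, ncol(dT))
  dX[ctx$srcmap[nz], ] <- dP[nz, , drop = FALSE]
  dX
}

## ---- windowed multi-head self-attention ----------------------------------

## p: list with Wq,Wk,Wv,Wo (d x d), bq,bk,bv,bo (d), relbias ((2w-1)^2 x heads)
attnFwd <- function(X, p, ctx, heads) {
  d <- ncol(X)
  dk <- d %/% heads
  Q <- denseFwd(X, p$Wq, p$bq)
  K <- denseFwd(X, p$Wk, p$bk)
  V <- denseFwd(X, p$Wv, p$bv)
  Qt <- winGather(Q, ctx); Kt <- winGather(K, ctx); Vt <- winGather(V, ctx)
  w2 <- ctx$win^2
  Ot <- matrix(0, nrow(Qt), d)
  Acache <- vector("list", ctx$nwin * heads)
  Bh <- lapply(seq_len(heads), function(hd)
    matrix(p$relbias[ctx$relidx, hd], w2, w2))
  for (wi in seq_len(ctx$nwin)) {
    rowsw <- ((wi - 1L) * w2 + 1L):(wi * w2)
    for (hd in seq_len(heads)) {
      colsd <- ((hd - 1L) * dk + 1L):(hd * dk)
      q <- Qt[rowsw, colsd, drop = FALSE]
      k <- Kt[rowsw, colsd, drop = FALSE]
      v <- Vt[rowsw, colsd, drop = FALSE]
      logits <- q %*% t(k) / sqrt(dk) + Bh[[hd]]
      if (!is.null(ctx$masks)) logits <- logits + ctx$masks[[wi]]
      A <- exp(logits - max(logits))       # scalar-max stabilisation
      A <- A / rowSums(A)
      Ot[rowsw, colsd] <- A %*% v
      Acache[[(wi - 1L) * heads + hd]] <- A
    }
  }
  O <- winScatter(Ot, ctx)
  Y <- denseFwd(O, p$Wo, p$bo)
  list(Y = Y, X = X, Q = Q, K = K, V = V, Qt = Qt, Kt = Kt, Vt = Vt,
       O = O, A = Acache)
}

attnBwd <- function(dY, cache, p, ctx, heads, gacc, prefix) {
  d <- ncol(cache$X)
  dk <- d %/% heads
  w2 <- ctx$win^2
  bo <- denseBwd(dY, cache$O, p$Wo)
  addGrad(gacc, paste0(prefix, ".Wo"), bo$dW)
  addGrad(gacc, paste0(prefix, ".bo"), bo$db)
  dOt <- winGather(bo$dX, ctx)   # gather is the adjoint of scatter
  dQt <- matrix(0, nrow(dOt), d)
  dKt <- matrix(0, nrow(dOt), d)
  dVt <- matrix(0, nrow(dOt), d)
  dRel <- matrix(0, (2L * ctx$win - 1L)^2, heads)
  dBh <- lapply(seq_len(heads), function(hd) matrix(0, w2, w2))
  for (wi in seq_len(ctx$nwin)) {
    rowsw <- ((wi - 1L) * w2 + 1L):(wi * w2)
    for (hd in seq_len(heads)) {
      colsd <- ((hd - 1L) * dk + 1L):(hd * dk)
      A <- cache$A[[(wi - 1L) * heads + hd]]
      q <- cache$Qt[rowsw, colsd, drop = FALSE]
      k <- cache$Kt[rowsw, colsd, drop = FALSE]
      v <- cache$Vt[rowsw, colsd, drop = FALSE]
      dO <- dOt[rowsw, colsd, drop = FALSE]
      dA <- dO %*% t(v)
      dVt[rowsw, colsd] <- dVt[rowsw, colsd] + t(A) %*% dO
      dlog <- A * (dA - rowSums(dA * A))
      dQt[rowsw, colsd] <- dQt[rowsw, colsd] + dlog %*% k / sqrt(dk)
      dKt[rowsw, colsd] <- dKt[rowsw, colsd] + t(dlog) %*% q / sqrt(dk)
      dBh[[hd]] <- dBh[[hd]] + dlog
    }
  }
  for (hd in seq_len(heads))
    dRel[, hd] <- rowsum(as.vector(dBh[[hd]]), as.vector(ctx$relidx))[, 1L]
  addGrad(gacc, paste0(prefix, ".relbias"), dRel)
  dQ <- winScatter(dQt, ctx); dK <- winScatter(dKt, ctx); dV <- winScatter(dVt, ctx)
  bq <- denseBwd(dQ, cache$X, p$Wq)
  bk <- denseBwd(dK, cache$X, p$Wk)
  bv <- denseBwd(dV, cache$X, p$Wv)
  addGrad(gacc, paste0(prefix, ".Wq"), bq$dW); addGrad(gacc, paste0(prefix, ".bq"), bq$db)
  addGrad(gacc, paste0(prefix, ".Wk"), bk$dW); addGrad(gacc, paste0(prefix, ".bk"), bk$db)
  addGrad(gacc, paste0(prefix, ".Wv"), bv$dW); addGrad(gacc, paste0(prefix, ".bv"), bv$db)
  bq$dX + bk$dX + bv$dX
}

## ---- pooled pyramid helpers (fusion) -------------------------------------

poolCtx <- function(h, w, f) {
  key <- paste("pool", h, w, f, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  hs <- ceiling(h / f); ws <- ceiling(w / f)
  ri <- (seq_len(h) - 1L) %/% f + 1L
  ci <- (seq_len(w) - 1L) %/% f + 1L
  g <- as.vector(outer(ri, (ci - 1L) * hs, `+`))
  cnt <- as.vector(rowsum(rep(1, length(g)), g))
  ctx <- list(hs = hs, ws = ws, g = g, cnt = cnt)
  .fsr_cache[[key]] <- ctx
  ctx
}

avgPoolFwd <- function(X, ctx) rowsum(X, ctx$g) / ctx$cnt
avgPoolBwd <- function(dP, ctx) dP[ctx$g, , drop = FALSE] / ctx$cnt[ctx$g]

## 1-D linear interpolation matrix (n_out x n_in), centre-aligned, clamped.
linInterpMatrix <- function(n_in, n_out) {
  key <- paste("lin", n_in, n_out, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    j0 <- floor(src); frac <- src - j0
    j0c <- min(max(j0, 1L), n_in)
    j1c <- min(max(j0 + 1L, 1L), n_in)
    M[i, j0c] <- M[i, j0c] + (1 - frac)
    M[i, j1c] <- M[i, j1c] + frac
  }
  .fsr_cache[[key]] <- M
  M
}

bilinearUpFwd <- function(P, hs, ws, h, w) {
  Mh <- linInterpMatrix(hs, h)
  Mw <- linInterpMatrix(ws, w)
  d <- ncol(P)
  U <- matrix(0, h * w, d)
  for (ch in seq_len(d))
    U[, ch] <- as.vector(Mh %*% matrix(P[, ch], hs, ws) %*% t(Mw))
  U
}

bilinearUpBwd <- function(dU, hs, ws, h, w) {
  Mh <- linInterpMatrix(hs, h)
  Mw <- linInterpMatrix(ws, w)
  d <- ncol(dU)
  dP <- matrix(0, hs * ws, d)
  for (ch in seq_len(d))
    dP[, ch] <- as.vector(t(Mh) %*% matrix(dU[, ch], h, w) %*% Mw)
  dP
}

## ---- pixel shuffle (depth-to-space x2) -----------------------------------

pixelShuffleCtx <- function(h, w) {
  key <- paste("ps", h, w, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  h2 <- 2L * h
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  outpos <- vector("list", 4L)
  s <- 1L
  for (dc in 0:1) for (dr in 0:1) {
    outpos[[s]] <- (2L * (rr - 1L) + 1L + dr) + (2L * (cc - 1L) + dc) * h2
    s <- s + 1L
  }
  ctx <- list(h = h, w = w, outpos = outpos)
  .fsr_cache[[key]] <- ctx
  ctx
}

## X: (h*w) x (4d) with channel layout (ch-1)*4 + sub -> returns (2h*2w) x d
pixelShuffleFwd <- function(X, ctx) {
  d <- ncol(X) %/% 4L
  Y <- matrix(0, 4L * ctx$h * ctx$w, d)
  for (s in 1:4) {
    cols <- seq.int(s, by = 4L, length.out = d)
    Y[ctx$outpos[[s]], ] <- X[, cols, drop = FALSE]
  }
  Y
}

pixelShuffleBwd <- function(dY, ctx) {
  d <- ncol(dY)
  dX <- matrix(0, ctx$h * ctx$w, 4L * d)
  for (s in 1:4) {
    cols <- seq.int(s, by = 4L, length.out = d)
    dX[, cols] <- dY[ctx$outpos[[s]], , drop = FALSE]
  }
  dX
}
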