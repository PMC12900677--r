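## Low-level array utilities shared by every module: image coercion,
## padding/index maps, cached im2col contexts for 2-D convolution (forward
## and backward), separable Gaussian blur, and Keys bicubic resampling.
## Images are plain numeric arrays H x W x C with values in [0, 1];
## grayscale matrices are accepted anywhere and promoted to H x W x 1.

.fsr_cache <- new.env(parent = emptyenv())

#' Coerce to a valid image array
#'
#' Promotes a numeric matrix to an `H x W x 1` array and validates the
#' package-wide image contract: finite values in `[0, 1]`, at least 8 pixels
#' per side, 1 or 3 channels.
#'
#' @param x Numeric matrix (grayscale) or `H x W x C` array with `C` 1 or 3.
#' @param check Validate the value range and minimum size (default `TRUE`).
#' @return A numeric `H x W x C` array.
#' @export
asImage <- function(x, check = TRUE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("image must be a matrix or an H x W x C array", call. = FALSE)
  if (!dim(x)[3] %in% c(1L, 3L))
    stop("image must have 1 or 3 channels, got ", dim(x)[3], call. = FALSE)
  if (check) {
    if (any(!is.finite(x)))
      stop("image contains non-finite values", call. = FALSE)
    if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
      stop("image values must lie in [0, 1]", call. = FALSE)
    if (dim(x)[1] < 8L || dim(x)[2] < 8L)
      stop("image must be at least 8 x 8 pixels", call. = FALSE)
  }
  x
}

#' @rdname asImage
#' @export
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert an image to a grayscale matrix
#'
#' RGB images are reduced with the Rec. 601 luminance weights
#' (0.299, 0.587, 0.114); grayscale input is returned as a matrix.
#'
#' @param img Image array.
#' @return Numeric `H x W` matrix.
#' @export
toGray <- function(img) {
  img <- asImage(img, check = FALSE)
  if (dim(img)[3] == 1L) return(img[, , 1L])
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

## green channel carries most vessel contrast in fundus photographs
greenChannel <- function(img) {
  img <- asImage(img, check = FALSE)
  if (dim(img)[3] == 1L) img[, , 1L] else img[, , 2L]
}

flipH <- function(img) {
  img <- asImage(img, check = FALSE)
  img[, dim(img)[2]:1, , drop = FALSE]
}

flipV <- function(img) {
  img <- asImage(img, check = FALSE)
  img[dim(img)[1]:1, , , drop = FALSE]
}

rot90Img <- function(img, k = 1L) {
  img <- asImage(img, check = FALSE)
  k <- k %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    d <- dim(img)
    out <- array(0, c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- t(img[d[1]:1, , ch])
    img <- out
  }
  img
}

## Run expr with a local RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## ---- padding -------------------------------------------------------------

## Reflect (mirror, no edge repeat) a 1-based coordinate vector into 1..n.
reflectCoord <- function(x, n) {
  if (n == 1L) return(rep.int(1L, length(x)))
  period <- 2L * (n - 1L)
  x <- (x - 1L) %% period
  x <- ifelse(x >= n, period - x, x)
  x + 1L
}

## Linear index map from a padded (h+2r) x (w+2r) grid into the source h x w
## grid (column-major), mode "reflect" or "zero".  Zero mode returns 0 for
## out-of-range positions.
padIndexMap <- function(h, w, r, mode = "reflect") {
  rows <- seq_len(h + 2L * r) - r
  cols <- seq_len(w + 2L * r) - r
  if (mode == "reflect") {
    ri <- reflectCoord(rows, h)
    ci <- reflectCoord(cols, w)
    as.vector(outer(ri, (ci - 1L) * h, `+`))
  } else {
    ri <- ifelse(rows >= 1L & rows <= h, rows, NA_integer_)
    ci <- ifelse(cols >= 1L & cols <= w, cols, NA_integer_)
    m <- outer(ri, (ci - 1L) * h, `+`)
    m[is.na(m)] <- 0L
    as.vector(m)
  }
}

## Pad a matrix by r pixels on every side.
padMatrix <- function(m, r, mode = "reflect") {
  h <- nrow(m); w <- ncol(m)
  map <- padIndexMap(h, w, r, mode)
  v <- as.vector(m)
  out <- numeric(length(map))
  nz <- map > 0L
  out[nz] <- v[map[nz]]
  matrix(out, h + 2L * r, w + 2L * r)
}

## ---- im2col convolution context ------------------------------------------

## Cached context for k x k convolution on an h x w grid.  `padmap` maps
## padded linear indices to source indices; `idx` is (h*w) x k^2 of padded
## linear indices, one column per kernel tap (row-major tap order
## (dr, dc) looping dc outer).
convCtx <- function(h, w, k, mode = "reflect") {
  key <- paste("conv", h, w, k, mode, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (k - 1L) %/% 2L
  hp <- h + 2L * r; wp <- w + 2L * r
  padmap <- padIndexMap(h, w, r, mode)
  pos <- as.vector(outer(seq_len(h) + r - 1L, (seq_len(w) + r - 1L) * hp,
                         function(i, j) i + j - hp + 1L))
  ## pos: padded linear index of the centre of each output position
  rows0 <- rep(seq_len(h) + r, times = w)
  cols0 <- rep(seq_len(w) + r, each = h)
  taps <- expand.grid(dr = -r:r, dc = -r:r)
  idx <- matrix(0L, h * w, k * k)
  for (t in seq_len(k * k)) {
    idx[, t] <- (rows0 + taps$dr[t]) + (cols0 + taps$dc[t] - 1L) * hp
  }
  ctx <- list(h = h, w = w, k = k, r = r, hp = hp, wp = wp,
              padmap = padmap, idx = idx, mode = mode)
  .fsr_cache[[key]] <- ctx
  ctx
}

## Build the padded feature matrix P ((hp*wp) x d) from X ((h*w) x d).
padFeatures <- function(X, ctx) {
  nz <- ctx$padmap > 0L
  P <- matrix(0, ctx$hp * ctx$wp, ncol(X))
  P[nz, ] <- X[ctx$padmap[nz], , drop = FALSE]
  P
}

## im2col: returns (h*w) x (k^2 * d) matrix, tap index fastest within channel.
im2col <- function(X, ctx) {
  d <- ncol(X)
  P <- padFeatures(X, ctx)
  A <- P[as.vector(ctx$idx), , drop = FALSE]  # (hw*k2) x d
  matrix(A, ctx$h * ctx$w, ctx$k * ctx$k * d)
}

## Forward k x k convolution.  W is (k^2*din) x dout, b length dout.
## Returns list(Y, Col) with Col cached for the backward pass.
conv2dForward <- function(X, W, b, ctx) {
  Col <- im2col(X, ctx)
  Y <- Col %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, Col = Col)
}

## Permutation turning W ((k2*din) x dout) into the flipped-kernel operator
## W2 ((k2*dout) x din) used for the backward-through-input convolution.
convFlipIndex <- function(k2, din, dout) {
  key <- paste("flip", k2, din, dout, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- integer(k2 * dout * din)
  pos <- 1L
  for (cin in seq_len(din)) {
    for (out in seq_len(dout)) {
      for (t in seq_len(k2)) {
        idx[pos] <- (cin - 1L) * k2 + (k2 + 1L - t) + (out - 1L) * k2 * din
        pos <- pos + 1L
      }
    }
  }
  .fsr_cache[[key]] <- idx
  idx
}

## Backward pass: given dY ((hw) x dout), cached Col, weights and ctx,
## returns dX ((hw) x din), dW, db.  The input gradient is computed as a
## correlation of dY with the flipped kernel, which is exact for zero
## padding; for reflective contexts a scatter-add over the pad map is used.
conv2dBackward <- function(dY, W, Col, ctx, din, computeDX = TRUE) {
  k2 <- ctx$k * ctx$k
  dW <- if (is.null(Col)) NULL else crossprod(Col, dY)
  db <- if (is.null(Col)) NULL else colSums(dY)
  if (!computeDX) return(list(dX = NULL, dW = dW, db = db))
  dout <- ncol(dY)
  if (ctx$mode == "zero") {
    W2 <- matrix(W[convFlipIndex(k2, din, dout)], k2 * dout, din)
    dX <- im2col(dY, ctx) %*% W2
  } else {
    dCol <- dY %*% t(W)                  # (hw) x (k2*din)
    dP <- matrix(0, ctx$hp * ctx$wp, din)
    for (t in seq_len(k2)) {
      cols <- t + k2 * (seq_len(din) - 1L)
      tgt <- ctx$idx[, t]
      dP[tgt, ] <- dP[tgt, , drop = FALSE] + dCol[, cols, drop = FALSE]
    }
    nz <- ctx$padmap > 0L
    dX <- rowsum(dP[nz, , drop = FALSE], group = ctx$padmap[nz])
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- separable Gaussian blur ---------------------------------------------

gaussKernel1d <- function(sigma) {
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-rad):rad
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Blur a matrix with reflective padding; sigma = 0 is the identity.
gaussBlurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussKernel1d(sigma)
  rad <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  ## rows
  rp <- reflectCoord(seq_len(h + 2L * rad) - rad, h)
  mp <- m[rp, , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k)) out <- out + k[t] * mp[t:(t + h - 1L), , drop = FALSE]
  ## cols
  cp <- reflectCoord(seq_len(w + 2L * rad) - rad, w)
  mp <- out[, cp, drop = FALSE]
  out2 <- matrix(0, h, w)
  for (t in seq_along(k)) out2 <- out2 + k[t] * mp[, t:(t + w - 1L), drop = FALSE]
  out2
}

#' Gaussian blur with reflective padding
#'
#' Separable isotropic Gaussian filter, kernel truncated at three standard
#' deviations and renormalised, so constant images are preserved exactly.
#' `sigma = 0` returns the input unchanged.
#'
#' @param img Image array or matrix.
#' @param sigma Standard deviation in pixels.
#' @return Image of the same shape.
#' @export
gaussBlur <- function(img, sigma) {
  wasmat <- is.matrix(img)
  img <- asImage(img, check = FALSE)
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- gaussBlurMatrix(img[, , ch], sigma)
  if (wasmat) out[, , 1L] else out
}

## ---- bicubic (Keys a = -0.5) resampling ----------------------------------

cubicKernel <- function(x) {
  a <- -0.5
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

## Dense 1-D resampling matrix (n_out x n_in).  When shrinking and
## `antialias`, the kernel is widened by the scale factor (imresize-style).
resizeMatrix1d <- function(n_in, n_out, antialias = TRUE) {
  key <- paste("rs", n_in, n_out, antialias, sep = "_")
  hit <- .fsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  scale <- n_in / n_out
  ks <- if (antialias && scale > 1) scale else 1
  width <- 2 * ks
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    lo <- floor(src - width); hi <- ceiling(src + width)
    j <- lo:hi
    wgt <- cubicKernel((j - src) / ks)
    keep <- wgt != 0
    j <- j[keep]; wgt <- wgt[keep]
    if (!length(j)) { j <- round(src); wgt <- 1 }
    wgt <- wgt / sum(wgt)
    jc <- pmin(pmax(j, 1L), n_in)     # clamp taps at the borders
    for (t in seq_along(jc)) M[i, jc[t]] <- M[i, jc[t]] + wgt[t]
  }
  .fsr_cache[[key]] <- M
  M
}

#' Bicubic resampling
#'
#' Separable Keys bicubic interpolation (a = -0.5) with centre-aligned
#' sampling and clamped borders. When shrinking, the kernel is widened by the
#' scale factor (antialiasing) unless `antialias = FALSE`. Rows of the
#' resampling operator sum to one, so constant images are preserved exactly.
#'
#' @param img Image array or matrix.
#' @param out_h,out_w Output dimensions in pixels.
#' @param antialias Widen the kernel when downscaling (default `TRUE`).
#' @param clip Clip the result to `[0, 1]` (default `TRUE`).
#' @return Resampled image, same number of channels.
#' @export
bicubicResize <- function(img, out_h, out_w, antialias = TRUE, clip = TRUE) {
  wasmat <- is.matrix(img)
  img <- asImage(img, check = FALSE)
  d <- dim(img)
  Mh <- resizeMatrix1d(d[1], out_h, antialias)
  Mw <- resizeMatrix1d(d[2], out_w, antialias)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Mh %*% img[, , ch] %*% t(Mw)
  if (clip) out <- clip01(out)
  if (wasmat) out[, , 1L] else out
}

## feature-matrix <-> image conversions (column-major position order)
img2feat <- function(img) {
  img <- asImage(img, check = FALSE)
  d <- dim(img)
  matrix(img, d[1] * d[2], d[3])
}

feat2img <- function(X, h, w) {
  array(X, c(h, w, ncol(X)))
}
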