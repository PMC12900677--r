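## The degradation model for LR synthesis and the six robustness protocols.

#' Synthesise a low-resolution image from a high-resolution one
#'
#' Bicubic downsampling by `s` followed by a Gaussian blur applied to the
#' downsampled image (that order is the degradation model adopted here;
#' `preBlur = TRUE` switches to the more common blur-then-downsample order).
#'
#' @param hr HR image; dimensions must be divisible by `s`.
#' @param s Integer scale, 2 or 4.
#' @param blurSigma Blur standard deviation in pixels (default 1.0);
#'   0 gives a pure bicubic downsample.
#' @param preBlur Blur before downsampling instead of after.
#' @return LR image in `[0, 1]`.
#' @export
prepareLR <- function(hr, s = 2L, blurSigma = 1.0, preBlur = FALSE) {
  hr <- asImage(hr, check = FALSE)
  d <- dim(hr)
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    stop("HR dimensions must be divisible by the scale (crop first)", call. = FALSE)
  if (preBlur && blurSigma > 0) hr <- gaussBlur(hr, blurSigma)
  lr <- bicubicResize(hr, d[1] %/% s, d[2] %/% s)
  if (!preBlur && blurSigma > 0) lr <- clip01(gaussBlur(lr, blurSigma))
  lr
}

## Normalised 1-px-wide line kernel of odd length at the given angle,
## rasterised by symmetric midpoint stepping from the centre; the step is
## scaled so the kernel spans kernelLen taps along its dominant axis
## (45 degrees gives the full 11-tap diagonal).
motionKernel <- function(kernelLen, angle) {
  if (kernelLen %% 2L == 0L) stop("kernelLen must be odd", call. = FALSE)
  k <- matrix(0, kernelLen, kernelLen)
  c0 <- (kernelLen + 1L) %/% 2L
  theta <- angle * pi / 180
  dx <- cos(theta); dy <- sin(theta)
  m <- max(abs(dx), abs(dy))
  half <- (kernelLen - 1L) / 2
  for (t in seq(-half, half, by = 0.5)) {
    r <- round(c0 + t * dy / m); cc <- round(c0 + t * dx / m)
    if (r >= 1 && r <= kernelLen && cc >= 1 && cc <= kernelLen) k[r, cc] <- 1
  }
  k / sum(k)
}

## Dense 2-D convolution with reflective padding (small kernels only).
convolve2dReflect <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  rp <- reflectCoord(seq_len(h + 2L * rh) - rh, h)
  cp <- reflectCoord(seq_len(w + 2L * rw) - rw, w)
  mp <- m[rp, cp, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (kernel[i, j] == 0) next
    out <- out + kernel[i, j] * mp[i:(i + h - 1L), j:(j + w - 1L), drop = FALSE]
  }
  out
}

#' Apply a degradation to an image
#'
#' Implements the degradation kinds of [DegradationSpec-class]:
#' \describe{
#'   \item{bicubic_down}{bicubic downsample by `scale`.}
#'   \item{gaussian_blur}{isotropic Gaussian, sd `sigma`, reflective padding.}
#'   \item{motion_blur}{normalised 1-px line kernel of length `kernelLen`
#'     at `angle` degrees.}
#'   \item{gaussian_noise}{additive i.i.d. noise, sd `sigma / 255` on the
#'     `[0,1]` scale, seeded by `seed`, clipped.}
#'   \item{jpeg}{encode/decode round trip at `quality` through the baseline
#'     JPEG codec.}
#'   \item{vignette}{multiply by `1 - strength * (r / rmax)^2`, `r` the
#'     distance to the image centre, `rmax` the half-diagonal.}
#'   \item{combined}{apply `subSpecs` in order.}
#' }
#'
#' @param img Image array or matrix in `[0, 1]`.
#' @param spec A [DegradationSpec-class].
#' @return Degraded image in `[0, 1]`, same shape (except `bicubic_down`).
#' @export
applyDegradation <- function(img, spec) {
  validObject(spec)
  wasmat <- is.matrix(img)
  img <- asImage(img, check = FALSE)
  d <- dim(img)
  out <- switch(spec@kind,
    bicubic_down = {
      if (d[1] %% spec@scale != 0L || d[2] %% spec@scale != 0L)
        stop("dimensions not divisible by scale", call. = FALSE)
      bicubicResize(img, d[1] %/% spec@scale, d[2] %/% spec@scale)
    },
    gaussian_blur = gaussBlur(img, spec@sigma),
    motion_blur = {
      if (spec@kernelLen == 1L) img
      else {
        k <- motionKernel(spec@kernelLen, spec@angle)
        o <- img
        for (ch in seq_len(d[3])) o[, , ch] <- convolve2dReflect(img[, , ch], k)
        o
      }
    },
    gaussian_noise = {
      if (spec@sigma == 0) img
      else withLocalSeed(spec@seed,
        img + array(rnorm(prod(d), 0, spec@sigma / 255), d))
    },
    jpeg = {
      rgb <- if (d[3] == 1L) array(rep(img, 3L), c(d[1], d[2], 3L)) else img
      ## low quality factors trigger a harmless codec caution
      raw <- suppressWarnings(
        jpeg::writeJPEG(rgb, raw(), quality = spec@quality / 100))
      dec <- jpeg::readJPEG(raw)
      if (d[3] == 1L) array(toGray(dec), c(d[1], d[2], 1L)) else dec
    },
    vignette = {
      ctrR <- (d[1] + 1) / 2; ctrC <- (d[2] + 1) / 2
      rmax2 <- (d[1] - ctrR)^2 + (d[2] - ctrC)^2
      fall <- 1 - spec@strength *
        outer((seq_len(d[1]) - ctrR)^2, (seq_len(d[2]) - ctrC)^2, `+`) / rmax2
      o <- img
      for (ch in seq_len(d[3])) o[, , ch] <- img[, , ch] * fall
      o
    },
    combined = {
      o <- img
      for (s2 in spec@subSpecs) o <- asImage(applyDegradation(o, s2), check = FALSE)
      o
    },
    stop("unknown degradation kind: ", spec@kind, call. = FALSE))
  out <- clip01(out)
  if (wasmat && dim(out)[3] == 1L) out[, , 1L] else out
}

#' The six-protocol robustness degradation suite
#'
#' Named specs with the protocol parameters: Gaussian blur sd 1.2; motion
#' blur, 11-pixel kernel at 45 degrees; Gaussian noise sd 25 (8-bit scale);
#' JPEG quality 20; 30% radial vignetting; and a combined protocol composing
#' blur, noise, JPEG and vignette in that order (physical acquisition order:
#' optics, sensor, compression, display).
#'
#' @param noiseSeed Seed for the noise members (default 0).
#' @return Named list of six [DegradationSpec-class] objects.
#' @export
protocolSuite <- function(noiseSeed = 0L) {
  blur <- degradationSpec("gaussian_blur", sigma = 1.2)
  motion <- degradationSpec("motion_blur", kernelLen = 11L, angle = 45)
  noise <- degradationSpec("gaussian_noise", sigma = 25, seed = noiseSeed)
  jpg <- degradationSpec("jpeg", quality = 20L)
  vig <- degradationSpec("vignette", strength = 0.30)
  comb <- degradationSpec("combined", subSpecs = list(blur, noise, jpg, vig))
  list(gaussian_blur = blur, motion_blur = motion, gaussian_noise = noise,
       jpeg = jpg, vignette = vig, combined = comb)
}

#' Noise severity ladder
#'
#' The Gaussian-noise severity grid used for robustness sweeps: clean (0),
#' low (10), medium (25), high (35), severe (50), on the 8-bit sigma scale.
#'
#' @return Ascending numeric vector of sigma values.
#' @export
noiseSeverityGrid <- function() c(0, 10, 25, 35, 50)

#' Serialise / deserialise degradation specs as JSON-ready lists
#'
#' @param spec A [DegradationSpec-class].
#' @return `specAsList`: a named list; `specFromList`: a `DegradationSpec`.
#' @export
specAsList <- function(spec) {
  out <- list(kind = spec@kind, scale = spec@scale, sigma = spec@sigma,
              kernel_len = spec@kernelLen, angle = spec@angle,
              quality = spec@quality, strength = spec@strength,
              seed = spec@seed)
  if (spec@kind == "combined") out$sub_specs <- lapply(spec@subSpecs, specAsList)
  out
}

#' @rdname specAsList
#' @param x A named list as produced by `specAsList`.
#' @export
specFromList <- function(x) {
  degradationSpec(kind = x$kind,
                  scale = x$scale %||% 2L, sigma = x$sigma %||% 0,
                  kernelLen = x$kernel_len %||% 1L, angle = x$angle %||% 0,
                  quality = x$quality %||% 90L, strength = x$strength %||% 0,
                  seed = x$seed %||% 0L,
                  subSpecs = lapply(x$sub_specs %||% list(), specFromList))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
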