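## Image I/O and pixel-fidelity metrics.

#' Read a PNG or TIFF image
#'
#' Values are scaled to `[0, 1]` by the source bit depth (the readers already
#' return this scale). A 4-channel image has its alpha channel stripped with
#' a warning; 2-channel (gray + alpha) likewise keeps only the gray plane.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Image array `H x W x C`, `C` in `{1, 3}`.
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)",
         call. = FALSE))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  nc <- dim(x)[3]
  if (nc == 4L) {
    warning("stripping alpha channel")
    x <- x[, , 1:3, drop = FALSE]
  } else if (nc == 2L) {
    warning("stripping alpha channel")
    x <- x[, , 1L, drop = FALSE]
  } else if (!nc %in% c(1L, 3L)) {
    stop("unsupported channel count: ", nc, call. = FALSE)
  }
  asImage(x)
}

#' Write an image as PNG or TIFF
#'
#' Quantisation is round-half-away-from-zero: a stored level is
#' `floor(v * (2^bits - 1) + 0.5)`, so 0.5 maps to 128 at 8 bits. 16-bit
#' output requires TIFF (the PNG writer in use is 8-bit).
#'
#' @param img Image array or matrix in `[0, 1]`.
#' @param path Output path; format chosen by extension.
#' @param bitDepth 8 or 16.
#' @export
writeImage <- function(img, path, bitDepth = 8L) {
  img <- asImage(img)
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16", call. = FALSE)
  maxv <- 2^bitDepth - 1
  q <- floor(img * maxv + 0.5) / maxv   # fixed round-half-away-from-zero rule
  ext <- tolower(tools::file_ext(path))
  out <- if (dim(q)[3] == 1L) q[, , 1L] else q
  ok <- switch(ext,
    png = {
      if (bitDepth == 16L)
        stop("16-bit output requires TIFF", call. = FALSE)
      png::writePNG(out, target = path)
      TRUE
    },
    tif = ,
    tiff = {
      tiff::writeTIFF(out, path, bits.per.sample = as.integer(bitDepth))
      TRUE
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(ok)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(dataRange^2 / MSE)` with the mean squared error taken jointly
#' over all pixels and channels. Identical images return the sentinel `Inf`.
#'
#' @param a,b Images of identical shape.
#' @param dataRange Value range of the data (default 1).
#' @return PSNR in dB, `Inf` for identical inputs.
#' @export
psnr <- function(a, b, dataRange = 1) {
  a <- asImage(a, check = FALSE); b <- asImage(b, check = FALSE)
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  if (dataRange <= 0) stop("dataRange must be > 0", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11x11 Gaussian window (sd 1.5) with the standard
#' stabilisers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. RGB inputs are first
#' reduced to luminance with the Rec. 601 weights (see [toGray()]).
#'
#' @param a,b Images of identical shape, at least 11 pixels per side.
#' @param dataRange Value range `L` (default 1).
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, dataRange = 1) {
  a <- asImage(a, check = FALSE); b <- asImage(b, check = FALSE)
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  x <- toGray(a); y <- toGray(b)
  if (min(dim(x)) < 11L) stop("image smaller than the 11x11 SSIM window", call. = FALSE)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  f <- function(m) gaussBlurMatrix(m, 1.5)   # 11-tap kernel at 3-sigma truncation
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2
  syy <- f(y * y) - my^2
  sxy <- f(x * y) - mx * my
  smap <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(smap)
}

#' PSNR retention under degradation
#'
#' Percentage of clean-image PSNR retained: `100 * degraded / clean`.
#'
#' @param clean PSNR on clean input, dB, must be positive and finite.
#' @param degraded PSNR on degraded input, dB.
#' @return Retention percentage.
#' @export
retentionPct <- function(clean, degraded) {
  if (!is.finite(clean) || !is.finite(degraded))
    stop("retention requires finite PSNR values", call. = FALSE)
  if (clean <= 0) stop("clean PSNR must be > 0", call. = FALSE)
  100 * degraded / clean
}
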