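## Synthetic fundus-like images with exact vessel ground truth, calibration
## patterns of analytically known fractal dimension, and paired LR/HR
## dataset assembly.

## Stamp soft/hard disc coverage of one centreline sample onto accumulators.
.stampSample <- function(acc, x, y, radius) {
  n <- nrow(acc$soft)
  r0 <- max(1L, floor(y - radius - 1)); r1 <- min(n, ceiling(y + radius + 1))
  c0 <- max(1L, floor(x - radius - 1)); c1 <- min(n, ceiling(x + radius + 1))
  if (r0 > r1 || c0 > c1) return(acc)
  rows <- r0:r1; cols <- c0:c1
  dmat <- sqrt(outer((rows - y)^2, (cols - x)^2, `+`))
  soft <- pmin(pmax(radius + 0.5 - dmat, 0), 1)
  acc$soft[rows, cols] <- pmax(acc$soft[rows, cols], soft)
  acc$hard[rows, cols] <- pmax(acc$hard[rows, cols], (dmat <= radius) * 1)
  acc
}

#' Generate a synthetic fundus image with exact vessel ground truth
#'
#' Renders recursively branching vessel trees from root points on the rim of
#' a circular field of view toward the centre. Vessels are darker than the
#' bright textured background (the fundus convention), with the vessel signal
#' written to the RGB channels at relative strengths (0.8, 1.0, 0.6) so the
#' green channel carries the most contrast, as in real fundus photographs.
#' The image uses anti-aliased (soft-coverage) strokes; the mask is the hard
#' rasterisation of the same strokes, giving unambiguous ground truth.
#' Output is deterministic per seed.
#'
#' @param params A [VesselTreeParams-class].
#' @return A [SyntheticFundus-class].
#' @export
generateFundus <- function(params) {
  validObject(params)
  n <- params@imageSize
  ctr <- (n + 1) / 2
  R <- params@fovRadiusFrac * n / 2
  withLocalSeed(params@seed, {
    acc <- list(soft = matrix(0, n, n), hard = matrix(0, n, n))
    truncated <- FALSE

    ## depth-first growth of one segment and its children
    grow <- function(x, y, heading, width, depth) {
      if (depth > params@maxDepth) return()
      if (width < 0.5) { truncated <<- TRUE; return() }
      seglen <- n * runif(1, 0.10, 0.18) * 0.9^depth
      wavelen <- runif(1, 0.5, 1) * seglen
      phase <- runif(1, 0, 2 * pi)
      ts <- seq(0, seglen, by = 0.5)
      dx <- cos(heading); dy <- sin(heading)
      lat <- params@tortuosityAmp * sin(2 * pi * ts / wavelen + phase)
      lat <- lat - lat[1]                      # segments join continuously
      px <- x + ts * dx - lat * dy
      py <- y + ts * dy + lat * dx
      keep <- ((px - ctr)^2 + (py - ctr)^2) <= (R - 1)^2
      if (!any(keep)) return()
      last <- max(which(keep))
      for (i in seq_len(last)) acc <<- .stampSample(acc, px[i], py[i], width / 2)
      if (last < length(ts)) return()          # left the field of view
      endx <- px[last]; endy <- py[last]
      if (depth == params@maxDepth) return()
      if (runif(1) < params@branchProb) {
        split <- runif(1, 0.25, 0.55)
        grow(endx, endy, heading + split + rnorm(1, 0, params@angleJitter / 2),
             width * params@widthDecay, depth + 1L)
        grow(endx, endy, heading - split + rnorm(1, 0, params@angleJitter / 2),
             width * params@widthDecay, depth + 1L)
      } else {
        grow(endx, endy, heading + rnorm(1, 0, params@angleJitter),
             width * sqrt(params@widthDecay), depth + 1L)
      }
    }

    for (i in seq_len(params@nRoots)) {
      theta <- 2 * pi * (i - 1) / params@nRoots +
        runif(1, -0.5, 0.5) * 2 * pi / params@nRoots
      rx <- ctr + (R - 2) * cos(theta)
      ry <- ctr + (R - 2) * sin(theta)
      heading <- atan2(ctr - ry, ctr - rx) + rnorm(1, 0, params@angleJitter)
      grow(rx, ry, heading, params@initialWidth, 1L)
    }
    if (truncated)
      warning("vessel width fell below 0.5 px before maxDepth; depth truncated")

    ## bright mottled background, dark vessels, mild noise
    mottle <- gaussBlurMatrix(matrix(rnorm(n * n, 0, 1), n, n), n / 32)
    mottle <- 0.08 * mottle / max(abs(mottle), 1e-12)
    bg <- params@backgroundLevel + mottle
    chanScale <- c(0.8, 1.0, 0.6)
    img <- array(0, c(n, n, 3L))
    noise <- array(rnorm(n * n * 3L, 0, params@textureNoiseSd), c(n, n, 3L))
    for (ch in 1:3) {
      img[, , ch] <- bg * (0.55 + 0.45 * chanScale[ch]) -
        params@vesselDarkness * chanScale[ch] * acc$soft + noise[, , ch]
    }
    img <- clip01(img)
    dist2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
    fov <- dist2 <= R^2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * fov
    mask <- acc$hard * fov
    new("SyntheticFundus", image = img, mask = mask, params = params)
  })
}

#' Calibration patterns of analytically known fractal dimension
#'
#' Binary masks whose box-counting dimension is known in closed form:
#' a one-pixel line (dimension 1), a filled square (2), a Sierpinski
#' triangle (log 3 / log 2), and a unit-cell checkerboard (2). For the
#' Sierpinski pattern, `iterations` subdivision levels are rendered as filled
#' cells of side `size / 2^iterations`; box-counting fits restricted to boxes
#' no smaller than that cell side recover the analytic dimension exactly
#' (`minBox` in the return value).
#'
#' @param pattern One of `"line"`, `"filled_square"`, `"sierpinski"`,
#'   `"checkerboard"`.
#' @param size Image side in pixels; must be a power of two for
#'   `"sierpinski"`.
#' @param iterations Subdivision levels for `"sierpinski"` (>= 1).
#' @return List with `mask` (binary matrix), `analyticDimension`, and
#'   `minBox` (smallest box side at which the pattern scales as analysed).
#' @export
generateCalibration <- function(pattern = c("line", "filled_square",
                                            "sierpinski", "checkerboard"),
                                size = 512L, iterations = 7L) {
  pattern <- match.arg(pattern)
  size <- as.integer(size)
  if (pattern == "sierpinski") {
    if (bitwAnd(size, size - 1L) != 0L)
      stop("sierpinski size must be a power of two", call. = FALSE)
    if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
    iterations <- min(iterations, as.integer(log2(size)))
    cell <- size %/% as.integer(2^iterations)
    ij <- seq_len(size) - 1L
    blk <- ij %/% cell
    mask <- outer(blk, blk, function(i, j) (bitwAnd(i, j) == 0L) * 1)
    return(list(mask = mask, analyticDimension = log(3) / log(2),
                minBox = cell))
  }
  mask <- switch(pattern,
    line = { m <- matrix(0, size, size); m[size %/% 2L, ] <- 1; m },
    filled_square = matrix(1, size, size),
    checkerboard = outer(seq_len(size), seq_len(size),
                         function(i, j) ((i + j) %% 2L) * 1))
  dim_analytic <- switch(pattern, line = 1, filled_square = 2, checkerboard = 2)
  list(mask = mask, analyticDimension = dim_analytic, minBox = 1L)
}

#' Build a paired LR/HR synthetic dataset
#'
#' Generates `n` synthetic fundus images (one derived seed per item), pairs
#' each with a low-resolution counterpart produced by the given degradation
#' specs applied in order, and assigns train/validation split flags by a
#' seeded shuffle.
#'
#' @param n Number of image pairs (>= 1).
#' @param paramsTemplate [VesselTreeParams-class] template; the seed slot is
#'   re-derived per item from `seed`.
#' @param scale Integer super-resolution factor for the pairing.
#' @param degradation List of [DegradationSpec-class] applied in order to the
#'   HR image to produce the LR image. An empty list falls back to a plain
#'   bicubic downsample (with a warning).
#' @param seed Integer master seed.
#' @param splitFrac Fraction of items flagged `"train"` (default 0.8).
#' @return List of items, each `list(hr = SyntheticFundus, lr = image array,
#'   split = "train"|"val")`, with attributes `scale` and `seed`.
#' @export
makeDataset <- function(n, paramsTemplate = vesselTreeParams(), scale = 2L,
                        degradation = list(
                          degradationSpec("bicubic_down", scale = scale),
                          degradationSpec("gaussian_blur", sigma = 1.0)),
                        seed = 0L, splitFrac = 0.8) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    p <- paramsTemplate
    p@seed <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
    hr <- generateFundus(p)
    lr <- hr@image
    if (!length(degradation)) {
      warning("empty degradation list; pairing by plain bicubic downsample")
      d <- dim(lr)
      lr <- bicubicResize(lr, d[1] %/% scale, d[2] %/% scale)
    } else {
      for (spec in degradation) {
        s2 <- spec
        if (s2@kind == "gaussian_noise")
          s2@seed <- as.integer((as.numeric(s2@seed) + i * 7919) %% 2147483647)
        lr <- applyDegradation(lr, s2)
      }
    }
    items[[i]] <- list(hr = hr, lr = lr, split = NA_character_)
  }
  nTrain <- round(splitFrac * n)
  ord <- withLocalSeed(seed, sample.int(n))
  for (j in seq_len(n))
    items[[ord[j]]]$split <- if (j <= nTrain) "train" else "val"
  attr(items, "scale") <- as.integer(scale)
  attr(items, "seed") <- as.integer(seed)
  items
}
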