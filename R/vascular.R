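## Vessel extraction, box-counting fractal dimension, and the clinical
## preservation metrics (fractal-dimension difference, vessel connectivity
## index, vessel tortuosity preservation).

.checkMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask values must be exactly {0,1}", call. = FALSE)
  mask
}

## 8-connected component labelling of a binary matrix via igraph.
## Returns an integer matrix of labels (0 = background).
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask > 0)
  lab <- matrix(0L, h, w)
  if (!length(idx)) return(lab)
  pos <- matrix(0L, h, w); pos[idx] <- seq_along(idx)
  ri <- (idx - 1L) %% h + 1L
  ci <- (idx - 1L) %/% h + 1L
  edges <- NULL
  for (dd in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- ri + dd[1]; c2 <- ci + dd[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (!any(ok)) next
    nb <- pos[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(pos[idx[ok]][hit], nb[hit]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(memb)
  lab
}

## Separable box-mean filter with reflective padding (odd window).
boxMeanMatrix <- function(m, window) {
  rad <- (window - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  rp <- reflectCoord(seq_len(h + 2L * rad) - rad, h)
  mp <- m[rp, , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_len(window)) out <- out + mp[t:(t + h - 1L), , drop = FALSE]
  cp <- reflectCoord(seq_len(w + 2L * rad) - rad, w)
  mp <- out[, cp, drop = FALSE]
  out2 <- matrix(0, h, w)
  for (t in seq_len(window)) out2 <- out2 + mp[, t:(t + w - 1L), drop = FALSE]
  out2 / window^2
}

#' Extract a binary vessel mask from a fundus image
#'
#' The green channel (or the gray channel) is inverted so vessels are bright,
#' thresholded against a local box-mean with a fixed offset, cleaned by a
#' morphological opening with a 3x3 cross, and filtered for small connected
#' components. Pixels outside the circular field of view (estimated from
#' near-zero pixels and shrunk by a safety margin) are excluded.
#'
#' @param img Image array or grayscale matrix.
#' @param window Local-mean window in pixels (odd; default 25).
#' @param offset Threshold offset above the local mean (default 0.02).
#' @param open Apply the 3x3 cross opening (default `TRUE`).
#' @param minComponent Remove components smaller than this pixel count
#'   (default 20; 0 disables).
#' @param fovExclude Exclude the estimated field-of-view border (default `TRUE`).
#' @return Binary `H x W` matrix (empty, with a warning, for contrast-free input).
#' @export
extractVessels <- function(img, window = 25L, offset = 0.02, open = TRUE,
                           minComponent = 20L, fovExclude = TRUE) {
  g <- greenChannel(img)
  if (max(g) - min(g) < 1e-9) {
    warning("image has no contrast; returning empty mask")
    return(matrix(0, nrow(g), ncol(g)))
  }
  inv <- 1 - g
  th <- (inv > boxMeanMatrix(inv, window) + offset) * 1
  if (fovExclude) {
    fov <- (toGray(img) > 0.02) * 1
    if (mean(fov) < 0.999) {
      ## shrink so the rim gradient is not picked up as vessel
      fov <- EBImage::erode(fov, EBImage::makeBrush(9L, "disc"))
    }
    th <- th * fov
  }
  if (open) th <- EBImage::opening(th, EBImage::makeBrush(3L, "diamond"))
  if (minComponent > 0L && any(th > 0)) {
    lab <- labelComponents(th)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minComponent)
    th <- (lab %in% keep) * 1
    dim(th) <- dim(lab)
  }
  th
}

#' Box-counting analysis of a binary mask
#'
#' Partitions the mask into grids of box side `eps` for `eps` running over
#' powers of two in `[minBox, maxBox]` (the mask is zero-padded to a
#' multiple of the largest box), counts boxes containing at least one vessel
#' pixel, and fits the slope of `log N(eps)` against `log(1/eps)` by least
#' squares.
#'
#' @param mask Binary matrix, non-empty.
#' @param minBox Smallest box side (power of two, >= 1).
#' @param maxBox Largest box side (power of two); default the largest power
#'   of two not exceeding `min(dim)/2`.
#' @return A [BoxCountResult-class].
#' @export
boxCount <- function(mask, minBox = 1L, maxBox = NULL) {
  mask <- .checkMask(mask)
  if (sum(mask) == 0) stop("empty mask: fractal dimension undefined", call. = FALSE)
  mn <- min(dim(mask))
  if (is.null(maxBox)) maxBox <- 2L^floor(log2(mn / 2))
  minBox <- as.integer(minBox); maxBox <- as.integer(maxBox)
  for (b in c(minBox, maxBox))
    if (b < 1L || bitwAnd(b, b - 1L) != 0L)
      stop("box sizes must be powers of two >= 1", call. = FALSE)
  if (maxBox > mn / 2) stop("maxBox exceeds min(H,W)/2", call. = FALSE)
  sizes <- 2L^(as.integer(log2(minBox)):as.integer(log2(maxBox)))
  if (length(sizes) < 3L)
    stop("fewer than 3 usable box-size levels", call. = FALSE)
  ## zero-pad to a multiple of the largest box so every level divides evenly
  hP <- ceiling(nrow(mask) / maxBox) * maxBox
  wP <- ceiling(ncol(mask) / maxBox) * maxBox
  occ <- matrix(0, hP, wP)
  occ[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  counts <- integer(length(sizes))
  cur <- 1L
  for (i in seq_along(sizes)) {
    while (cur < sizes[i]) {     # halve occupancy grid down to this level
      nr <- nrow(occ); nc <- ncol(occ)
      occ <- pmax(occ[seq(1L, nr, 2L), , drop = FALSE],
                  occ[seq(2L, nr, 2L), , drop = FALSE])
      occ <- pmax(occ[, seq(1L, nc, 2L), drop = FALSE],
                  occ[, seq(2L, nc, 2L), drop = FALSE])
      cur <- cur * 2L
    }
    counts[i] <- sum(occ > 0)
  }
  x <- log(1 / sizes)
  y <- log(counts)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  r2 <- if (stats::var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else 1
  new("BoxCountResult", boxSizes = as.numeric(sizes), counts = as.numeric(counts),
      df = slope, fitR2 = r2, flagged = slope < 0 || slope > 2.2)
}

#' Fractal dimension of an image or mask
#'
#' For an image, runs [extractVessels()] first; a binary-matrix input
#' bypasses extraction. Default box range `[1, min(H,W)/4]`.
#'
#' @param x Image array or binary mask matrix.
#' @param minBox,maxBox Box range passed to [boxCount()].
#' @param ... Extraction arguments forwarded to [extractVessels()].
#' @return Numeric fractal dimension estimate.
#' @export
fractalDimension <- function(x, minBox = 1L, maxBox = NULL, ...) {
  mask <- if (is.matrix(x) && all(x %in% c(0, 1))) x else extractVessels(x, ...)
  if (is.null(maxBox)) maxBox <- 2L^floor(log2(min(dim(mask)) / 4))
  boxCount(mask, minBox = minBox, maxBox = maxBox)@df
}

#' Fractal-dimension difference between a reference and an enhanced image
#'
#' `|Df(hr) - Df(sr)|` with both dimensions computed through the same
#' extraction and box-counting pipeline.
#'
#' @param hr,sr Images (or binary masks) of identical shape.
#' @param ... Forwarded to [fractalDimension()].
#' @return Non-negative numeric.
#' @export
deltaDf <- function(hr, sr, ...) {
  dh <- if (is.matrix(hr)) dim(hr) else dim(asImage(hr, check = FALSE))[1:2]
  ds <- if (is.matrix(sr)) dim(sr) else dim(asImage(sr, check = FALSE))[1:2]
  if (!identical(dh, ds)) stop("shape mismatch", call. = FALSE)
  abs(fractalDimension(hr, ...) - fractalDimension(sr, ...))
}

## ---- skeletonization -----------------------------------------------------

.shift <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Morphological thinning to a one-pixel skeleton
#'
#' Zhang-Suen thinning of a binary mask; iterates the two sub-steps until no
#' pixel changes.
#'
#' @param mask Binary matrix.
#' @return Binary matrix of centreline pixels.
#' @export
skeletonize <- function(mask) {
  m <- .checkMask(mask)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      ## neighbours clockwise from north: p2..p9
      p2 <- .shift(m, 1, 0);  p3 <- .shift(m, 1, 1)
      p4 <- .shift(m, 0, 1);  p5 <- .shift(m, -1, 1)
      p6 <- .shift(m, -1, 0); p7 <- .shift(m, -1, -1)
      p8 <- .shift(m, 0, -1); p9 <- .shift(m, 1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (ring[[i]] == 0 & ring[[i + 1]] == 1)
      cond <- m == 1 & bsum >= 2 & bsum <= 6 & a == 1
      if (step == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

## Decompose a skeleton into branches (paths between endpoints/junctions).
## Returns a data.frame with arc length, chord length and tortuosity per
## branch of arc length >= minLen.
skeletonBranches <- function(skel, minLen = 10) {
  ## crossing number: 0->1 transitions around the pixel; >= 3 marks a true
  ## bifurcation (plain 8-neighbour degree over-counts staircase corners)
  p2 <- .shift(skel, 1, 0);  p3 <- .shift(skel, 1, 1)
  p4 <- .shift(skel, 0, 1);  p5 <- .shift(skel, -1, 1)
  p6 <- .shift(skel, -1, 0); p7 <- .shift(skel, -1, -1)
  p8 <- .shift(skel, 0, -1); p9 <- .shift(skel, 1, -1)
  ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  trans <- matrix(0, nrow(skel), ncol(skel))
  for (i in 1:8) trans <- trans + (ring[[i]] == 0 & ring[[i + 1]] == 1)
  junction <- skel == 1 & trans >= 3
  body <- skel
  body[junction] <- 0
  lab <- labelComponents(body)
  nlab <- max(lab)
  res <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    if (length(idx) < 2L) next
    h <- nrow(skel)
    ri <- (idx - 1L) %% h + 1L
    ci <- (idx - 1L) %/% h + 1L
    ## degree within the component
    key <- paste(ri, ci)
    keyset <- new.env(parent = emptyenv())
    for (i in seq_along(idx)) assign(key[i], i, envir = keyset)
    nbrs <- function(i) {
      out <- integer()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        k <- paste(ri[i] + dr, ci[i] + dc)
        j <- keyset[[k]]
        if (!is.null(j)) out <- c(out, j)
      }
      out
    }
    degree <- vapply(seq_along(idx), function(i) length(nbrs(i)), integer(1))
    ends <- which(degree <= 1L)
    if (!length(ends)) next                       # closed loop: skip
    ## trace from one endpoint
    ordp <- integer(length(idx)); visited <- logical(length(idx))
    cur <- ends[1]; ordp[1] <- cur; visited[cur] <- TRUE
    for (s in 2:length(idx)) {
      nx <- setdiff(nbrs(cur), which(visited))
      if (!length(nx)) { ordp <- ordp[1:(s - 1)]; break }
      cur <- nx[1]; ordp[s] <- cur; visited[cur] <- TRUE
    }
    rs <- ri[ordp]; cs <- ci[ordp]
    arc <- sum(sqrt(diff(rs)^2 + diff(cs)^2))
    chord <- sqrt((rs[length(rs)] - rs[1])^2 + (cs[length(cs)] - cs[1])^2)
    if (arc >= minLen && chord > 0)
      res[[length(res) + 1L]] <- c(arc = arc, chord = chord, tau = arc / chord)
  }
  if (!length(res))
    return(data.frame(arc = numeric(), chord = numeric(), tau = numeric()))
  as.data.frame(do.call(rbind, res))
}

#' Vessel connectivity index
#'
#' Agreement in vascular network connectedness: both masks are skeletonised,
#' connected components of the skeletons are counted (8-connectivity), and
#' `VCI = 1 - |c_sr - c_hr| / max(c_sr, c_hr)`. Symmetric, in `[0, 1]`, and 1
#' for identical masks. (The index is this package's operationalisation of
#' connectivity agreement; see the methods vignette.)
#'
#' @param hrMask,srMask Binary masks of identical shape, both non-empty.
#' @return Numeric in `[0, 1]`.
#' @export
vci <- function(hrMask, srMask) {
  hrMask <- .checkMask(hrMask); srMask <- .checkMask(srMask)
  if (!identical(dim(hrMask), dim(srMask))) stop("shape mismatch", call. = FALSE)
  if (sum(hrMask) == 0 || sum(srMask) == 0)
    stop("vci undefined for empty masks", call. = FALSE)
  ch <- max(labelComponents(skeletonize(hrMask)))
  cs <- max(labelComponents(skeletonize(srMask)))
  1 - abs(cs - ch) / max(cs, ch)
}

#' Vessel tortuosity preservation
#'
#' Mean branch tortuosity (arc length / chord length over skeleton branches
#' of at least `minLen` pixels) is computed for both masks and compared:
#' `VTP = max(0, 1 - |tau_sr - tau_hr| / tau_hr)`. 1 for identical masks.
#' (Package operationalisation; see the methods vignette.)
#'
#' @param hrMask,srMask Binary masks of identical shape.
#' @param minLen Minimum branch arc length in pixels (default 10).
#' @return Numeric in `[0, 1]`.
#' @export
vtp <- function(hrMask, srMask, minLen = 10) {
  hrMask <- .checkMask(hrMask); srMask <- .checkMask(srMask)
  if (!identical(dim(hrMask), dim(srMask))) stop("shape mismatch", call. = FALSE)
  bh <- skeletonBranches(skeletonize(hrMask), minLen)
  bs <- skeletonBranches(skeletonize(srMask), minLen)
  if (!nrow(bh) || !nrow(bs))
    stop("no measurable skeleton branches (length >= ", minLen, ")", call. = FALSE)
  th <- mean(bh$tau); ts <- mean(bs$tau)
  max(0, 1 - abs(ts - th) / th)
}

#' Clinical category of a fractal-dimension difference
#'
#' Left-closed bins: `[0, 0.01)` excellent, `[0.01, 0.05)` acceptable,
#' `[0.05, 0.10)` moderate, `[0.10, Inf)` substantial.
#'
#' @param d Non-negative fractal-dimension difference.
#' @return Character label.
#' @export
classifyDeltaDf <- function(d) {
  if (!is.finite(d) || d < 0) stop("delta Df must be >= 0", call. = FALSE)
  if (d < 0.01) "excellent"
  else if (d < 0.05) "acceptable"
  else if (d < 0.10) "moderate"
  else "substantial"
}

#' Relative improvement percentage
#'
#' For lower-is-better metrics (the default, e.g. fractal-dimension
#' difference): `100 * (baseline - ours) / baseline`. For higher-is-better
#' metrics (e.g. connectivity): `100 * (ours - baseline) / baseline`.
#'
#' @param ours,baseline Metric values; `baseline` must be positive.
#' @param higherIsBetter Direction of the metric (default `FALSE`).
#' @return Percentage improvement.
#' @export
improvementPct <- function(ours, baseline, higherIsBetter = FALSE) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be > 0", call. = FALSE)
  if (higherIsBetter) 100 * (ours - baseline) / baseline
  else 100 * (baseline - ours) / baseline
}

#' Dice overlap of two binary masks
#'
#' @param a,b Binary masks of identical shape.
#' @return `2|A . B| / (|A| + |B|)`, or 1 when both masks are empty.
#' @export
diceOverlap <- function(a, b) {
  a <- .checkMask(a); b <- .checkMask(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a * b) / s
}

#' Read / write a binary mask as PNG
#'
#' @param mask Binary matrix.
#' @param path File path.
#' @export
writeMask <- function(mask, path) {
  .checkMask(mask)
  png::writePNG(mask, target = path)
  invisible(TRUE)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1
}
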