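# Shared fixtures, all generated in code.

seededImage <- function(seed, h = 32L, w = h, C = 3L) {
  set.seed(seed)
  array(runif(h * w * C), c(h, w, C))
}

# render a binary mask as a dark-on-bright image (fundus convention)
maskAsImage <- function(mask, bg = 0.9, dark = 0.6) {
  img <- array(0, c(dim(mask), 3L))
  for (ch in 1:3) img[, , ch] <- bg - dark * mask
  img
}

smallFundusParams <- function(seed = 0L) {
  vesselTreeParams(seed = seed, imageSize = 96L, nRoots = 3L, maxDepth = 4L,
                   initialWidth = 3)
}

smallDataset <- function(n = 6L, seed = 1L) {
  makeDataset(n, smallFundusParams(), scale = 2L, seed = seed)
}

# independent brute-force box counter: nested loops over the box grid
bruteBoxCount <- function(mask, eps) {
  hP <- ceiling(nrow(mask) / eps) * eps
  wP <- ceiling(ncol(mask) / eps) * eps
  m <- matrix(0, hP, wP)
  m[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  cnt <- 0L
  for (i in seq(1L, hP, by = eps)) {
    for (j in seq(1L, wP, by = eps)) {
      if (any(m[i:(i + eps - 1L), j:(j + eps - 1L)] > 0)) cnt <- cnt + 1L
    }
  }
  cnt
}
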