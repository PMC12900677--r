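test_that("box counts equal the brute-force nested-loop oracle exactly", {
  set.seed(11)
  for (rep in 1:4) {
    mask <- matrix(rbinom(64 * 64, 1, runif(1, 0.02, 0.3)), 64, 64)
    if (sum(mask) == 0) mask[5, 5] <- 1
    bc <- boxCount(mask, 1, 16)
    for (k in seq_along(bc@boxSizes)) {
      expect_identical(as.integer(bc@counts[k]),
                       bruteBoxCount(mask, as.integer(bc@boxSizes[k])))
    }
  }
})

test_that("box-count invariants: N(1) is the pixel count, counts non-increasing", {
  set.seed(12)
  mask <- matrix(rbinom(64 * 64, 1, 0.1), 64, 64)
  bc <- boxCount(mask, 1, 16)
  expect_identical(as.integer(bc@counts[1]), as.integer(sum(mask)))
  expect_true(all(diff(bc@counts) <= 0))
  expect_false(bc@flagged)
  expect_error(boxCount(matrix(0, 64, 64)), "empty")
  expect_error(boxCount(mask, 8, 16), "3 usable")
  expect_error(boxCount(mask, 3, 16), "powers of two")
})

test_that("calibration patterns recover their analytic dimensions", {
  ln <- generateCalibration("line", 512)
  expect_equal(boxCount(ln$mask, 1, 128)@df, 1, tolerance = 0.05)
  sq <- generateCalibration("filled_square", 512)
  expect_equal(boxCount(sq$mask, 1, 128)@df, 2, tolerance = 0.05)
  sp <- generateCalibration("sierpinski", 512, 7)
  bc <- boxCount(sp$mask, sp$minBox, 128)
  expect_equal(bc@df, log(3) / log(2), tolerance = 0.08)
  expect_gt(bc@fitR2, 0.99)
})

test_that("df is invariant to translation within epsilon-aligned padding", {
  sp <- generateCalibration("sierpinski", 128, 5)
  base <- boxCount(sp$mask, 1, 32)@df
  shifted <- matrix(0, 256, 256)
  shifted[65:192, 65:192] <- sp$mask          # offset by a multiple of 32
  expect_equal(boxCount(shifted, 1, 32)@df, base, tolerance = 1e-12)
})

test_that("nearest-neighbour upscaling changes df by less than 0.1", {
  sp <- generateCalibration("sierpinski", 128, 5)
  up <- sp$mask[rep(seq_len(128), each = 2), rep(seq_len(128), each = 2)]
  expect_lt(abs(fractalDimension(up) - fractalDimension(sp$mask)), 0.1)
})

test_that("df is preserved under horizontal flip", {
  sp <- generateCalibration("sierpinski", 128, 5)
  expect_equal(fractalDimension(sp$mask[, 128:1]), fractalDimension(sp$mask),
               tolerance = 1e-12)
})

test_that("vessel extraction overlaps the generator ground truth", {
  f <- generateFundus(vesselTreeParams(seed = 0L))
  expect_gte(diceOverlap(extractVessels(f@image), f@mask), 0.7)
})

test_that("extraction of a constant image is empty, with a warning", {
  expect_warning(m <- extractVessels(array(0.5, c(64, 64, 3))), "contrast")
  expect_identical(sum(m), 0)
})

test_that("extraction commutes with horizontal flip", {
  f <- generateFundus(smallFundusParams(4L))
  a <- extractVessels(f@image[, 96:1, , drop = FALSE])
  b <- extractVessels(f@image)[, 96:1]
  expect_identical(a, b)
})

test_that("deltaDf identity, symmetry, and blur sensitivity", {
  f <- generateFundus(smallFundusParams(6L))
  expect_identical(deltaDf(f@image, f@image), 0)
  sp <- maskAsImage(generateCalibration("sierpinski", 128, 5)$mask)
  blur <- gaussBlur(sp, 3)
  expect_equal(deltaDf(sp, blur), deltaDf(blur, sp))
  expect_gt(deltaDf(sp, blur, open = FALSE, minComponent = 0), 0.05)
  expect_error(deltaDf(f@image, f@image[1:48, 1:48, , drop = FALSE]), "shape")
})

test_that("vci formula: identity, a single cut, symmetry", {
  m <- matrix(0, 64, 64); m[32, 5:60] <- 1
  expect_equal(vci(m, m), 1)
  m2 <- m; m2[32, 30:32] <- 0
  expect_equal(vci(m, m2), 0.5)              # 1 - |2 - 1| / 2
  expect_equal(vci(m2, m), vci(m, m2))
  expect_error(vci(m, matrix(0, 64, 64)), "empty")
})

test_that("vtp: identity is 1; straightened vessels score below 1", {
  m <- matrix(0, 64, 64); m[32, 5:60] <- 1
  expect_equal(vtp(m, m), 1)
  wob <- vesselTreeParams(seed = 5L, imageSize = 96L, nRoots = 2L,
                          maxDepth = 2L, branchProb = 0, initialWidth = 3,
                          tortuosityAmp = 3)
  straight <- wob; straight@tortuosityAmp <- 0
  a <- generateFundus(wob)@mask
  b <- generateFundus(straight)@mask
  expect_lt(vtp(a, b), 1)
  expect_error(vtp(matrix(0, 64, 64), m), "branches|empty")
})

test_that("clinical categories follow the left-closed bins and are monotone", {
  expect_identical(classifyDeltaDf(0), "excellent")
  expect_identical(classifyDeltaDf(0.0099), "excellent")
  expect_identical(classifyDeltaDf(0.01), "acceptable")
  expect_identical(classifyDeltaDf(0.0987), "moderate")
  expect_identical(classifyDeltaDf(0.1789), "substantial")
  ranks <- c(excellent = 1, acceptable = 2, moderate = 3, substantial = 4)
  cats <- ranks[sapply(c(0, 0.005, 0.02, 0.07, 0.12, 0.3), classifyDeltaDf)]
  expect_true(all(diff(cats) >= 0))
  expect_error(classifyDeltaDf(-0.1), ">= 0")
})

test_that("improvement percentages reproduce the printed comparisons", {
  expect_equal(round(improvementPct(0.0987, 0.1189), 1), 17.0)
  expect_equal(round(improvementPct(0.1789, 0.2089), 1), 14.4)
  expect_equal(round(improvementPct(0.8456, 0.8267, higherIsBetter = TRUE), 1), 2.3)
  expect_equal(improvementPct(0.5, 0.5), 0)
  expect_error(improvementPct(0.1, 0), "> 0")
})

test_that("skeletonization thins a thick stroke to a unit-width centreline", {
  m <- matrix(0, 64, 64); m[28:36, 5:60] <- 1
  sk <- skeletonize(m)
  expect_true(all(sk <= m))
  expect_lt(sum(sk), sum(m) / 3)
  # centreline is 8-connected and single-component
  expect_identical(max(fractalSR:::labelComponents(sk)), 1L)
})

test_that("masks survive a PNG round trip", {
  m <- generateCalibration("sierpinski", 64, 4)$mask
  f <- withr::local_tempfile(fileext = ".png")
  writeMask(m, f)
  expect_identical(readMask(f), m)
})
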