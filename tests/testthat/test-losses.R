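test_that("every loss component is zero at sr == hr and non-negative away", {
  f <- generateFundus(smallFundusParams(1L))
  hr <- f@image
  ps <- perceptualSpec()
  expect_identical(mseLoss(hr, hr), 0)
  expect_identical(perceptualLoss(hr, hr, ps), 0)
  expect_identical(fractalLoss(hr, hr, "soft"), 0)
  expect_identical(fractalLoss(hr, hr, "hard"), 0)
  sr <- clip01(gaussBlur(hr, 1.5))
  expect_gt(mseLoss(sr, hr), 0)
  expect_gte(perceptualLoss(sr, hr, ps), 0)
  expect_gte(fractalLoss(sr, hr, "soft"), 0)
})

test_that("mse has its closed forms and permutation invariance", {
  expect_equal(mseLoss(array(0, c(16, 16, 1)), array(0.5, c(16, 16, 1))), 0.25)
  a <- seededImage(2); b <- seededImage(3)
  expect_equal(mseLoss(a[, 32:1, , drop = FALSE], b[, 32:1, , drop = FALSE]),
               mseLoss(a, b))
  expect_error(mseLoss(a, seededImage(3, 16)), "shape")
})

test_that("an identity extractor collapses the perceptual loss to MSE", {
  a <- seededImage(4); b <- seededImage(5)
  expect_equal(perceptualLoss(a, b, perceptualSpec("identity")), mseLoss(a, b))
})

test_that("the perceptual extractor is deterministic in its seed", {
  a <- seededImage(6); b <- seededImage(7)
  v1 <- perceptualLoss(a, b, perceptualSpec(seed = 3L))
  v2 <- perceptualLoss(a, b, perceptualSpec(seed = 3L))
  v3 <- perceptualLoss(a, b, perceptualSpec(seed = 4L))
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
})

test_that("soft fractal loss converges to the hard pipeline as tau shrinks", {
  sp <- maskAsImage(generateCalibration("sierpinski", 64, 6)$mask)
  ln <- maskAsImage(generateCalibration("line", 64)$mask)
  hard <- fractalLoss(sp, ln, "hard", open = FALSE, minComponent = 0)
  gaps <- sapply(c(0.05, 0.01, 0.002), function(tau)
    abs(fractalLoss(sp, ln, "soft", tau) - hard))
  expect_true(all(diff(gaps) < 0))           # shrinking with temperature
  expect_lt(gaps[3], 0.02)
})

test_that("fractal loss is symmetric and guards degenerate inputs", {
  sp <- maskAsImage(generateCalibration("sierpinski", 64, 6)$mask)
  ln <- maskAsImage(generateCalibration("line", 64)$mask)
  expect_equal(fractalLoss(sp, ln, "soft"), fractalLoss(ln, sp, "soft"))
  flat <- array(0.5, c(64, 64, 3))
  expect_warning(v <- fractalLoss(flat, flat, "soft"), "flat")
  expect_identical(v, 0)
  expect_warning(expect_error(fractalLoss(flat, flat, "hard"), "empty|contrast"))
  tiny <- array(runif(8 * 8 * 3), c(8, 8, 3))   # < 3 box levels
  expect_warning(v2 <- fractalLoss(tiny, clip01(tiny + 0.1), "soft"), "small")
  expect_identical(v2, 0)
})

test_that("total loss recombines its components exactly", {
  f <- generateFundus(smallFundusParams(8L))
  hr <- f@image
  sr <- clip01(gaussBlur(hr, 1.2))
  ps <- perceptualSpec()
  w <- c(1, 0.1, 0.05)
  tl <- totalLoss(sr, hr, w, ps)
  expect_equal(tl$total, sum(w * tl$components))
  expect_equal(tl$components[["mse"]], mseLoss(sr, hr))
  expect_equal(tl$components[["perceptual"]], perceptualLoss(sr, hr, ps))
  # Table-style ablation configurations arise purely by zeroing weights
  mseOnly <- totalLoss(sr, hr, c(1, 0, 0), ps)
  expect_equal(mseOnly$total, mseLoss(sr, hr))
  expect_identical(mseOnly$components[["perceptual"]], 0)
  expect_identical(mseOnly$components[["fractal"]], 0)
  noPer <- totalLoss(sr, hr, c(1, 0, 0.05), ps)
  expect_equal(noPer$total, mseLoss(sr, hr) + 0.05 * tl$components[["fractal"]])
  expect_identical(totalLoss(hr, hr, w, ps)$total, 0)
})

test_that("the composite gradient matches finite differences", {
  set.seed(9)
  f <- generateFundus(smallFundusParams(9L))
  hr <- f@image[1:48, 1:48, , drop = FALSE]
  sr <- clip01(hr + array(rnorm(length(hr), 0, 0.05), dim(hr)))
  ps <- perceptualSpec()
  w <- c(1, 0.1, 0.05)
  tl <- totalLoss(sr, hr, w, ps, withGrad = TRUE)
  fn <- function(s) totalLoss(s, hr, w, ps)$total
  for (k in 1:5) {
    i <- sample(length(sr), 1); e <- 1e-6
    s2 <- sr
    s2[i] <- s2[i] + e; lp <- fn(s2)
    s2[i] <- s2[i] - 2 * e; lm <- fn(s2)
    expect_equal(tl$grad[i], (lp - lm) / (2 * e), tolerance = 1e-3)
  }
})

test_that("soft fractal gradient is non-zero for differing vascular density", {
  dense <- generateFundus(vesselTreeParams(seed = 1L, imageSize = 96L,
                                           nRoots = 4L, maxDepth = 5L,
                                           initialWidth = 3))@image
  sparse <- generateFundus(vesselTreeParams(seed = 1L, imageSize = 96L,
                                            nRoots = 1L, maxDepth = 2L,
                                            initialWidth = 3))@image
  g <- fractalSR:::.fractalGrad(sparse, dense)
  expect_gt(sum(abs(g)), 0)
  # and the loss is locally smooth along that direction
  l0 <- fractalLoss(sparse, dense, "soft")
  l1 <- fractalLoss(clip01(sparse - 1e-3 * g / max(abs(g))), dense, "soft")
  expect_lt(abs(l1 - l0), 0.05)
})
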