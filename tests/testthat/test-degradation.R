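test_that("prepareLR contracts: shape, zero-blur, constants, divisibility", {
  hr <- seededImage(1, 128)
  lr <- prepareLR(hr, 2L, blurSigma = 0)
  expect_identical(dim(lr)[1:2], c(64L, 64L))
  expect_equal(lr, bicubicResize(hr, 64, 64))        # sigma 0 is pure bicubic
  cst <- array(0.7, c(64, 64, 3))
  expect_equal(prepareLR(cst, 2L, blurSigma = 1.5), array(0.7, c(32, 32, 3)),
               tolerance = 1e-12)
  expect_error(prepareLR(seededImage(1, 63, 64), 2L), "divisible")
})

test_that("degradations hold their closed-form identities", {
  img <- seededImage(2, 33)
  expect_identical(applyDegradation(img, degradationSpec("gaussian_noise", sigma = 0)),
                   img)
  cst <- array(0.7, c(33, 33, 3))
  expect_equal(applyDegradation(cst, degradationSpec("motion_blur",
                                                     kernelLen = 11L, angle = 45)),
               cst, tolerance = 1e-12)
  v <- applyDegradation(array(1, c(33, 33, 3)),
                        degradationSpec("vignette", strength = 0.3))
  expect_equal(v[17, 17, 1], 1)                       # centre untouched
  expect_equal(v[1, 1, 1], 0.7, tolerance = 1e-12)    # corner: 1 - strength
})

test_that("every degradation maps [0,1] into [0,1]", {
  set.seed(5)
  suite <- protocolSuite()
  for (rep in 1:3) {
    img <- array(runif(40 * 40 * 3), c(40, 40, 3))
    for (nm in names(suite)) {
      out <- applyDegradation(img, suite[[nm]])
      expect_true(all(out >= 0 & out <= 1), info = nm)
    }
    out <- applyDegradation(img, degradationSpec("bicubic_down", scale = 2L))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("gaussian blur commutes with horizontal flip in the interior", {
  img <- seededImage(6, 48)
  a <- applyDegradation(img[, 48:1, , drop = FALSE],
                        degradationSpec("gaussian_blur", sigma = 1.2))
  b <- applyDegradation(img, degradationSpec("gaussian_blur", sigma = 1.2))
  b <- b[, 48:1, , drop = FALSE]
  interior <- 6:43
  expect_lt(max(abs(a[interior, interior, ] - b[interior, interior, ])), 1e-6)
})

test_that("seeded noise is bit-reproducible and scales as sigma/255", {
  img <- array(0.5, c(64, 64, 3))
  s1 <- applyDegradation(img, degradationSpec("gaussian_noise", sigma = 25, seed = 9L))
  s2 <- applyDegradation(img, degradationSpec("gaussian_noise", sigma = 25, seed = 9L))
  expect_identical(s1, s2)
  s3 <- applyDegradation(img, degradationSpec("gaussian_noise", sigma = 25, seed = 10L))
  expect_false(identical(s1, s3))
  # sample sd consistent with sigma/255 (no clipping bites at 0.5 +/- 0.1)
  expect_equal(sd(s1 - img), 25 / 255, tolerance = 0.02)
})

test_that("PSNR degrades monotonically with blur and noise severity", {
  img <- generateFundus(smallFundusParams(3L))@image
  pBlur <- sapply(c(0.5, 1, 2, 3), function(s)
    psnr(img, applyDegradation(img, degradationSpec("gaussian_blur", sigma = s))))
  expect_true(all(diff(pBlur) <= 0))
  pNoise <- sapply(c(5, 15, 30, 50), function(s)
    psnr(img, applyDegradation(img, degradationSpec("gaussian_noise",
                                                    sigma = s, seed = 1L))))
  expect_true(all(diff(pNoise) <= 0))
})

test_that("the six-protocol suite carries the protocol parameters", {
  suite <- protocolSuite()
  expect_length(suite, 6)
  expect_equal(suite$gaussian_blur@sigma, 1.2)
  expect_identical(suite$motion_blur@kernelLen, 11L)
  expect_equal(suite$motion_blur@angle, 45)
  expect_equal(suite$gaussian_noise@sigma, 25)
  expect_identical(suite$jpeg@quality, 20L)
  expect_equal(suite$vignette@strength, 0.30)
  expect_gte(length(suite$combined@subSpecs), 3)
  for (sp in suite) expect_true(isTRUE(validObject(sp, test = TRUE)))
})

test_that("noise severity ladder holds the sweep values, ascending", {
  g <- noiseSeverityGrid()
  expect_true(25 %in% g)
  expect_true(50 %in% g)
  expect_identical(g, sort(g))
  expect_equal(g[1], 0)
})

test_that("degradation specs survive a JSON round trip", {
  suite <- protocolSuite()
  for (nm in names(suite)) {
    back <- specFromList(jsonlite::fromJSON(
      jsonlite::toJSON(specAsList(suite[[nm]]), auto_unbox = TRUE),
      simplifyVector = FALSE))
    expect_identical(specAsList(back), specAsList(suite[[nm]]), info = nm)
  }
})

test_that("motion kernel is a normalized line; 45 degrees is the diagonal", {
  k <- fractalSR:::motionKernel(11L, 45)
  expect_equal(sum(k), 1)
  expect_true(all(diag(k) > 0))
  expect_error(fractalSR:::motionKernel(10L, 0), "odd")
})
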