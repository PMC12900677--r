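test_that("cosine schedule matches the closed form at the anchor epochs", {
  tc <- trainConfig(etaMax = 2e-4, etaMin = 1e-6, epochs = 300L)
  expect_equal(cosineLR(0, tc), 2e-4)
  expect_equal(cosineLR(300, tc), 1e-6)
  expect_equal(cosineLR(150, tc), (2e-4 + 1e-6) / 2)
  ts <- 0:300
  expect_equal(sapply(ts, cosineLR, cfg = tc),
               1e-6 + 0.5 * (2e-4 - 1e-6) * (1 + cos(ts * pi / 300)))
  expect_error(cosineLR(-1, tc), "out of")
  expect_error(cosineLR(301, tc), "out of")
})

test_that("augmentation: identity off, seeded determinism, multiset safety", {
  lr <- seededImage(1, 16); hr <- seededImage(2, 32)
  off <- augmentPair(lr, hr, seed = 5, flips = FALSE, rotate = FALSE,
                     jitter = FALSE)
  expect_identical(off$lr, lr)
  expect_identical(off$hr, hr)
  a <- augmentPair(lr, hr, seed = 7)
  b <- augmentPair(lr, hr, seed = 7)
  expect_identical(a, b)
  geo <- augmentPair(lr, hr, seed = 9, jitter = FALSE)
  expect_equal(sort(as.vector(geo$lr)), sort(as.vector(lr)))
  expect_equal(sort(as.vector(geo$hr)), sort(as.vector(hr)))
})

test_that("patch sampling aligns LR and HR crops exactly", {
  f <- generateFundus(smallFundusParams(3L))
  hr <- f@image
  lr <- prepareLR(hr, 2L, blurSigma = 0)
  ps <- samplePatches(lr, hr, n = 4, patch = 16, scale = 2, seed = 3)
  expect_length(ps, 4)
  for (p in ps) {
    expect_identical(dim(p$lr)[1:2], c(16L, 16L))
    expect_identical(dim(p$hr)[1:2], c(32L, 32L))
    # the bicubic-downsampled HR crop must land on the LR crop footprint
    expect_lt(mean(abs(bicubicResize(p$hr, 16, 16) - p$lr)), 0.05)
  }
  expect_identical(samplePatches(lr, hr, 4, 16, 2, seed = 3), ps)
  expect_error(samplePatches(lr, hr, 1, 64, 2, seed = 1), "smaller")
})

test_that("curriculum is piecewise constant with a harder second phase", {
  tc <- trainConfig(epochs = 10L, curriculumSwitch = 0.3)
  s0 <- curriculumStage(0, tc, 2L)
  expect_length(s0, 1)
  expect_identical(s0[[1]]@kind, "combined")
  expect_identical(curriculumStage(2, tc, 2L), s0)   # constant within phase 1
  s9 <- curriculumStage(9, tc, 2L)
  expect_gt(length(s9), 1)
  kinds <- vapply(s9, function(s) s@kind, character(1))
  expect_true("gaussian_noise" %in% kinds)
  expect_identical(curriculumStage(5, tc, 2L), s9)   # constant within phase 2
  expect_error(curriculumStage(10, tc, 2L), "epoch")
})

test_that("short training descends and improves on bicubic validation PSNR", {
  ds <- smallDataset(6, seed = 2)
  val <- Filter(function(it) it$split == "val", ds)
  bicubicPsnr <- mean(sapply(val, function(it)
    psnr(bicubicResize(it$lr, 96, 96), it$hr@image)))
  tc <- trainConfig(epochs = 2L, stepsPerEpoch = 60L, batch = 2L, patch = 16L,
                    seed = 0, lossWeights = c(1, 0, 0), curriculumSwitch = 1)
  res <- trainModel(srModel(tinyModelConfig(), seed = 0), ds, tc)
  h <- historyRecords(res$history)
  expect_identical(nrow(h), 2L)
  expect_lt(h$loss[2], h$loss[1])
  expect_gt(h$valPsnr[2], bicubicPsnr)
  # logged learning rates follow the closed form
  expect_equal(h$lr, sapply(h$epoch - 1, cosineLR, cfg = tc))
})

test_that("equal seeds give bitwise-identical histories", {
  ds <- smallDataset(5, seed = 3)
  tc <- trainConfig(epochs = 2L, stepsPerEpoch = 15L, batch = 1L, patch = 16L,
                    seed = 4, lossWeights = c(1, 0.1, 0.05))
  h1 <- historyRecords(trainModel(srModel(tinyModelConfig(), 1), ds, tc)$history)
  h2 <- historyRecords(trainModel(srModel(tinyModelConfig(), 1), ds, tc)$history)
  expect_identical(h1, h2)
})

test_that("interrupted-then-resumed training matches the uninterrupted run", {
  ds <- smallDataset(5, seed = 5)
  tc <- trainConfig(epochs = 4L, stepsPerEpoch = 12L, batch = 1L, patch = 16L,
                    seed = 6, lossWeights = c(1, 0, 0), curriculumSwitch = 1)
  dirA <- withr::local_tempdir()
  full <- trainModel(srModel(tinyModelConfig(), 2), ds, tc, checkpointDir = dirA)
  dirB <- withr::local_tempdir()
  trainModel(srModel(tinyModelConfig(), 2), ds, tc, checkpointDir = dirB,
             maxEpochs = 2)                  # interrupted after epoch 2
  resumed <- trainModel(srModel(tinyModelConfig(), 2), ds, tc,
                        checkpointDir = dirB,
                        resumeFrom = file.path(dirB, "last.rds"))
  expect_identical(historyRecords(full$history),
                   historyRecords(resumed$history))
  expect_equal(resumed$model@params, full$model@params, tolerance = 1e-15)
})

test_that("loss components logged per epoch recombine to the logged total", {
  ds <- smallDataset(5, seed = 7)
  w <- c(1, 0.1, 0.05)
  tc <- trainConfig(epochs = 2L, stepsPerEpoch = 10L, batch = 1L, patch = 16L,
                    seed = 8, lossWeights = w)
  h <- historyRecords(trainModel(srModel(tinyModelConfig(), 3), ds, tc)$history)
  expect_equal(h$loss,
               w[1] * h$lossMse + w[2] * h$lossPerceptual + w[3] * h$lossFractal,
               tolerance = 1e-12)
})

test_that("training errors on empty splits", {
  ds <- smallDataset(5, seed = 9)
  for (i in seq_along(ds)) ds[[i]]$split <- "train"
  tc <- trainConfig(epochs = 1L, stepsPerEpoch = 2L, batch = 1L, patch = 16L)
  expect_error(trainModel(srModel(tinyModelConfig(), 0), ds, tc), "splits")
})
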