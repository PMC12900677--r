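# helper: tiny model with a non-zero (seeded) final conv so the whole
# network contributes to the output
tinyModelActive <- function(seed = 0L) {
  m <- srModel(tinyModelConfig(), seed = seed)
  set.seed(1)
  m@params[["up.final.W"]] <- matrix(rnorm(9 * 16 * 3, 0, 0.05), 9 * 16, 3)
  m
}

test_that("parameter count is exact, monotone in depth, superlinear in width", {
  cfg <- tinyModelConfig()
  m <- srModel(cfg, seed = 0)
  expect_identical(countParameters(cfg), sum(vapply(m@params, length, integer(1))))
  full <- modelConfig()
  mfull <- initParameters(full, seed = 0)
  expect_identical(countParameters(full), sum(vapply(mfull, length, integer(1))))
  deeper <- modelConfig(nRSTB = 7L)
  expect_gt(countParameters(deeper), countParameters(full))
  wider <- modelConfig(featureDim = 360L)
  expect_gt(countParameters(wider), 2 * countParameters(full))
})

test_that("a fresh model reproduces the bicubic baseline exactly", {
  m <- srModel(tinyModelConfig(), seed = 3)
  lr <- seededImage(5, 16)
  expect_equal(srForward(m, lr), bicubicResize(lr, 32, 32, clip = FALSE),
               tolerance = 1e-14)
})

test_that("zeroed transformer/CNN blocks reduce their paths to the identity", {
  m <- tinyModelActive()
  for (nm in names(m@params)) {
    if (grepl("^t1\\.", nm) || grepl("^c[12]\\.", nm))
      m@params[[nm]] <- m@params[[nm]] * 0
    if (grepl("ln[12]\\.g$", nm)) m@params[[nm]] <- rep(1, 16)  # keep LN valid
  }
  f0 <- shallowFeatures(m, seededImage(6, 16))
  expect_equal(transformerFeatures(m, f0), f0, tolerance = 1e-12)
  expect_equal(cnnFeatures(m, f0), f0, tolerance = 1e-12)
})

test_that("window attention matches a dense global-attention oracle", {
  cfg8 <- modelConfig(scale = 2, featureDim = 16, nRSTB = 1, stlPerRSTB = 2,
                      nRCAB = 1, window = 8, heads = 2, mlpRatio = 2,
                      caReduction = 4, fusionScales = 1)
  m8 <- srModel(cfg8, seed = 1)
  set.seed(2)
  f <- array(rnorm(8 * 8 * 16, 0, 0.5), c(8, 8, 16))
  out <- windowAttention(m8, f, shift = 0)
  # dense oracle: one window covering the whole 8x8 map
  p <- m8@params; dk <- 8
  X <- matrix(f, 64, 16)
  lin <- function(W, b) X %*% p[[W]] + rep(p[[b]], each = 64)
  Q <- lin("t1.s1.attn.Wq", "t1.s1.attn.bq")
  K <- lin("t1.s1.attn.Wk", "t1.s1.attn.bk")
  V <- lin("t1.s1.attn.Wv", "t1.s1.attn.bv")
  wctx <- fractalSR:::windowCtx(8, 8, 8, 0)
  O <- matrix(0, 64, 16)
  for (hd in 1:2) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    B <- matrix(p[["t1.s1.attn.relbias"]][wctx$relidx, hd], 64, 64)
    L <- Q[wctx$perm, cols] %*% t(K[wctx$perm, cols]) / sqrt(dk) + B
    A <- exp(L - apply(L, 1, max)); A <- A / rowSums(A)
    expect_equal(rowSums(A), rep(1, 64), tolerance = 1e-12)  # softmax rows
    O[wctx$perm, cols] <- A %*% V[wctx$perm, cols]
  }
  Yexp <- O %*% p[["t1.s1.attn.Wo"]] + rep(p[["t1.s1.attn.bo"]], each = 64)
  expect_lt(max(abs(matrix(out, 64, 16) - Yexp)), 1e-5)
})

test_that("attention output is linear in V: zero V projection gives zero", {
  m <- tinyModelActive()
  m@params[["t1.s1.attn.Wv"]] <- m@params[["t1.s1.attn.Wv"]] * 0
  m@params[["t1.s1.attn.bv"]] <- m@params[["t1.s1.attn.bv"]] * 0
  m@params[["t1.s1.attn.bo"]] <- m@params[["t1.s1.attn.bo"]] * 0
  set.seed(3)
  f <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  expect_equal(max(abs(windowAttention(m, f, shift = 0))), 0)
})

test_that("channel attention follows its closed form", {
  m <- tinyModelActive()
  set.seed(4)
  f <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  # zero weights, zero bias: gate is sigmoid(0) = 0.5 everywhere
  m0 <- m
  for (nm in c("c1.ca.W1", "c1.ca.b1", "c1.ca.W2", "c1.ca.b2"))
    m0@params[[nm]] <- m0@params[[nm]] * 0
  expect_equal(channelAttention(m0, f), 0.5 * f, tolerance = 1e-12)
  # gates always within (0, 1): |output| strictly below |input| off zeros
  ca <- fractalSR:::.caForward(matrix(f, 256, 16), m@params, "c1.ca")
  expect_true(all(ca$a > 0 & ca$a < 1))
  # spatially constant channels stay constant
  fc <- array(rep(seq_len(16), each = 256), c(16, 16, 16))
  out <- channelAttention(m, fc)
  expect_equal(max(apply(out, 3, function(ch) diff(range(ch)))), 0)
})

test_that("fusion with one scale and selection weights passes ft through", {
  cfg <- modelConfig(scale = 2, featureDim = 16, nRSTB = 1, stlPerRSTB = 2,
                     nRCAB = 1, window = 4, heads = 2, mlpRatio = 2,
                     caReduction = 4, fusionScales = 1)
  m <- srModel(cfg, seed = 0)
  m@params[["fuse.s1.W"]] <- rbind(diag(16), matrix(0, 16, 16))
  m@params[["fuse.s1.b"]] <- numeric(16)
  set.seed(5)
  ft <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  fc <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  expect_equal(fuseFeatures(m, ft, fc), ft, tolerance = 1e-12)
  expect_identical(dim(fuseFeatures(srModel(cfg, 1), ft, fc))[3], 16L)
})

test_that("reconstruction scales by s and x4 stacks two shuffle stages", {
  lr <- seededImage(7, 16)
  m2 <- srModel(tinyModelConfig(scale = 2L), seed = 0)
  expect_identical(dim(srForward(m2, lr)), c(32L, 32L, 3L))
  m4 <- srModel(tinyModelConfig(scale = 4L), seed = 0)
  expect_identical(dim(srForward(m4, lr)), c(64L, 64L, 3L))
  expect_equal(srForward(m4, lr), bicubicResize(lr, 64, 64, clip = FALSE),
               tolerance = 1e-14)             # zero-init final conv
})

test_that("forward handles non-window-multiple sizes via internal padding", {
  m <- tinyModelActive()
  lr <- seededImage(8, 13, 11)
  sr <- srForward(m, lr)
  expect_identical(dim(sr), c(26L, 22L, 3L))
  expect_true(all(is.finite(sr)))
})

test_that("forward is deterministic and matches the frozen golden checksum", {
  m <- tinyModelActive(seed = 0L)
  set.seed(42)
  lr <- array(runif(16 * 16 * 3), c(16, 16, 3))
  sr1 <- srForward(m, lr)
  sr2 <- srForward(m, lr)
  expect_identical(sr1, sr2)
  expect_equal(sum(sr1), 1581.3141279590, tolerance = 1e-8)
  expect_equal(sr1[5, 7, 2], 0.4998267463, tolerance = 1e-8)
  f0 <- shallowFeatures(m, lr)
  expect_equal(sum(transformerFeatures(m, f0)), -644.0322680713, tolerance = 1e-6)
  expect_equal(sum(cnnFeatures(m, f0)), 804.6290436786, tolerance = 1e-6)
})

test_that("shallow features keep spatial dims and respect linearity", {
  m <- tinyModelActive()
  lr <- seededImage(9, 20, 24)
  f0 <- shallowFeatures(m, lr)
  expect_identical(dim(f0), c(20L, 24L, 16L))
  m0 <- m
  m0@params[["shallow.W"]] <- m0@params[["shallow.W"]] * 0
  m0@params[["shallow.b"]] <- m0@params[["shallow.b"]] * 0
  expect_equal(max(abs(shallowFeatures(m0, lr))), 0)
})

test_that("analytic gradients match finite differences across layer types", {
  cfg <- tinyModelConfig()
  m <- tinyModelActive()
  set.seed(10)
  lr <- array(runif(12 * 12 * 3), c(12, 12, 3))
  hr <- array(runif(24 * 24 * 3), c(24, 24, 3))
  lossFn <- function(p)
    mean((fractalSR:::.forwardInternal(cfg, p, lr, keepCache = FALSE)$sr - hr)^2)
  fw <- fractalSR:::.forwardInternal(cfg, m@params, lr, keepCache = TRUE)
  gacc <- new.env(parent = emptyenv())
  fractalSR:::.backwardInternal(cfg, m@params, fw$cache,
                                2 * (fw$sr - hr) / length(hr), gacc)
  groups <- c("shallow.W", "t1.s1.attn.Wq", "t1.s2.attn.relbias",
              "t1.s1.mlp.W1", "t1.conv.W", "c1.conv1.W", "c2.ca.W1",
              "fuse.s2.W", "up.s1.W", "up.final.W", "t1.s1.ln1.g")
  eps <- 1e-5
  for (nm in groups) {
    i <- which.max(abs(gacc[[nm]]))          # probe the strongest entry
    p2 <- m@params
    p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- lossFn(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- lossFn(p2)
    num <- (lp - lm) / (2 * eps)
    expect_equal(gacc[[nm]][i], num, tolerance = 1e-3, info = nm)
  }
})

test_that("gradients reach every parameter group (no dead paths)", {
  cfg <- tinyModelConfig()
  m <- tinyModelActive()
  set.seed(11)
  gacc <- new.env(parent = emptyenv())
  for (b in 1:2) {                            # a small seeded batch
    lr <- array(runif(16 * 16 * 3), c(16, 16, 3))
    hr <- array(runif(32 * 32 * 3), c(32, 32, 3))
    fw <- fractalSR:::.forwardInternal(cfg, m@params, lr, keepCache = TRUE)
    fractalSR:::.backwardInternal(cfg, m@params, fw$cache,
                                  2 * (fw$sr - hr) / length(hr), gacc)
  }
  expect_setequal(ls(gacc), names(m@params))
  norms <- vapply(names(m@params), function(n) sum(abs(gacc[[n]])), numeric(1))
  expect_true(all(norms > 0), info = paste(names(which(norms == 0)), collapse = ","))
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  m <- tinyModelActive()
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  back <- loadCheckpoint(f)
  expect_identical(back@params, m@params)
  expect_identical(fractalSR:::cfgAsList(back@config),
                   fractalSR:::cfgAsList(m@config))
  expect_error(loadCheckpoint(f, expectConfig = tinyModelConfig(scale = 4L)),
               "does not match")
})

test_that("single-path configurations drop the other path cleanly", {
  lr <- seededImage(12, 16)
  tOnly <- modelConfig(scale = 2, featureDim = 16, nRSTB = 1, stlPerRSTB = 2,
                       nRCAB = 0, window = 4, heads = 2, mlpRatio = 2,
                       caReduction = 4, fusionScales = 2)
  cOnly <- modelConfig(scale = 2, featureDim = 16, nRSTB = 0, stlPerRSTB = 2,
                       nRCAB = 2, window = 4, heads = 2, mlpRatio = 2,
                       caReduction = 4, fusionScales = 2)
  expect_identical(dim(srForward(srModel(tOnly, 0), lr)), c(32L, 32L, 3L))
  expect_identical(dim(srForward(srModel(cOnly, 0), lr)), c(32L, 32L, 3L))
  expect_error(modelConfig(nRSTB = 0L, nRCAB = 0L), "at least one path")
})
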