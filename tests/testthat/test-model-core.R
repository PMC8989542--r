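# The network itself: shapes, determinism, gradients, the prediction
# contract (reverse-complement averaging + detrending) and serialization.

test_that("configuration validation rejects shape-inconsistent residuals", {
  expect_error(irlstmConfig(stemFilters = 64L, branchFilters = 16L),
               "shape inconsistency")
  expect_error(irlstmConfig(dropout = 1.0), "dropout")
  cfg <- irlstmConfig()
  expect_equal(cfg$branch2Kernels, c(11L, 21L))
  expect_equal(cfg$lstmUnits, 20L)
})

test_that("the default architecture has the independently computed parameter count", {
  # layer-by-layer arithmetic, written out separately from the builder:
  # conv: K*Cin*Cout + Cout; BN: 2*C; LSTM: 4*(Cin*H + H*H + H); dense: H+1
  conv <- function(K, Cin, Cout) K * Cin * Cout + Cout
  bn <- function(C) 2 * C
  expected <- conv(3, 4, 64) + bn(64) +            # stem
    conv(3, 64, 32) + bn(32) + conv(3, 32, 32) + bn(32) +   # branch 1
    conv(11, 64, 32) + bn(32) + conv(21, 32, 32) + bn(32) + # branch 2
    bn(64) +                                        # post-residual BN
    4 * (64 * 20 + 20 * 20 + 20) +                  # LSTM
    20 + 1                                          # dense head
  m <- buildIRLSTM(seed = 1)
  expect_equal(nParams(m), expected)
  expect_equal(nParams(m), 61541L)
})

test_that("a zeroed network outputs exactly zero", {
  m <- tinyModel()
  m@params <- lapply(m@params, function(p) p * 0)
  X <- array(oneHotEncode(randomSeq(50)), c(50, 4, 1))
  expect_equal(predictRaw(m, X), 0)
})

test_that("forward evaluation is deterministic and batching-invariant", {
  m <- tinyModel()
  set.seed(5)
  X <- array(0, c(50, 4, 6))
  for (i in 1:6) X[, , i] <- oneHotEncode(randomSeq(50))
  o1 <- predictRaw(m, X)
  o2 <- predictRaw(m, X)
  expect_identical(o1, o2)
  single <- vapply(1:6, function(i) predictRaw(m, X[, , i]), numeric(1))
  expect_equal(o1, single, tolerance = 1e-6)
  expect_equal(predictRaw(m, X, chunk = 2L), o1)
  expect_error(predictRaw(m, X[1:30, , ]), "rows")
})

test_that("training mode with dropout is stochastic, evaluation mode is not", {
  cfg <- tinyConfig()
  set.seed(9)
  ini <- DNAbendR:::nnInit(cfg)
  X <- array(oneHotEncode(randomSeq(50)), c(50, 4, 1))
  m1 <- DNAbendR:::nnDropoutMasks(cfg, 1L)
  m2 <- DNAbendR:::nnDropoutMasks(cfg, 1L)
  t1 <- DNAbendR:::nnForward(ini$params, ini$bnStats, cfg, X,
                             training = TRUE, masks = m1)$out
  t2 <- DNAbendR:::nnForward(ini$params, ini$bnStats, cfg, X,
                             training = TRUE, masks = m2)$out
  expect_false(isTRUE(all.equal(t1, t2)))
  e1 <- DNAbendR:::nnForward(ini$params, ini$bnStats, cfg, X)$out
  e2 <- DNAbendR:::nnForward(ini$params, ini$bnStats, cfg, X)$out
  expect_identical(e1, e2)
})

test_that("analytic gradients match central finite differences", {
  cfg <- irlstmConfig(inputLength = 16L, stemFilters = 8L,
                      branchFilters = 4L, lstmUnits = 5L)
  set.seed(21)
  ini <- DNAbendR:::nnInit(cfg)
  B <- 3L
  X <- array(stats::runif(16 * 4 * B), c(16, 4, B))
  masks <- DNAbendR:::nnDropoutMasks(cfg, B)
  y <- c(0.5, -0.2, 1.0)
  fw <- DNAbendR:::nnForward(ini$params, ini$bnStats, cfg, X,
                             training = TRUE, masks = masks)
  bw <- DNAbendR:::nnBackward(ini$params, cfg, fw$cache,
                              2 * (fw$out - y) / B)
  loss <- function(params) {
    o <- DNAbendR:::nnForward(params, ini$bnStats, cfg, X,
                              training = TRUE, masks = masks)$out
    mean((o - y)^2)
  }
  eps <- 1e-6
  for (nm in names(ini$params)) {
    g <- as.numeric(bw$grads[[nm]])
    expect_equal(length(g), length(ini$params[[nm]]), info = nm)
    idx <- sample(length(g), min(4L, length(g)))
    for (i in idx) {
      pp <- ini$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- ini$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-4, info = nm)
    }
  }
})

test_that("predictCScore is reverse-complement invariant and applies the detrend", {
  m <- tinyModel()
  set.seed(13)
  seqs <- randomSeqs(100, 50)
  rcs <- vapply(seqs, function(s)
    as.character(reverseComplement(Biostrings::DNAString(s))), character(1))
  expect_equal(predictCScore(m, seqs), predictCScore(m, rcs),
               tolerance = 1e-6)
  # identity calibration: output equals the plain two-pass mean
  raw2 <- DNAbendR:::.rawAveraged(m, seqs[1:5])
  expect_equal(predictCScore(m, seqs[1:5]), raw2, tolerance = 1e-12)
  # a non-trivial detrend is applied affinely
  m@detrend <- c(a = 0.7, b = 2.5)
  expect_equal(predictCScore(m, seqs[1:5]), 0.7 + 2.5 * raw2,
               tolerance = 1e-12)
  expect_error(predictCScore(m, randomSeq(60)), "predictTrack")
})

test_that("standardized C-score 1.96 sits at the 97.5% normal quantile", {
  expect_equal(stats::pnorm(1.96), 0.975, tolerance = 1e-4)
})

test_that("model serialization round-trips to bit-identical predictions", {
  m <- tinyModel(seed = 31)
  m@detrend <- c(a = 0.1, b = 1.4)
  set.seed(17)
  seqs <- randomSeqs(20, 50)
  before <- predictCScore(m, seqs)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(predictCScore(m2, seqs), before)
  expect_equal(m2@seed, m@seed)
  # config JSON export carries the channel order
  j <- tempfile(fileext = ".json")
  writeModelConfigJSON(m, j)
  meta <- jsonlite::fromJSON(paste(readLines(j), collapse = ""))
  expect_equal(meta$channelOrder, c("A", "C", "G", "T"))
})
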