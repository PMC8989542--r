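test_that("the oracle scores its closed-form examples", {
  p <- oracleParams()
  # no WW dinucleotides and no A/T runs: score 0
  expect_equal(oracleScore(strrep("G", 50), p), 0)
  # poly-A 50-mer: P = 50 - 4 = 46, f_WW = 1, A = amplitude of a flat
  # indicator; evaluate the stated formula directly
  s <- strrep("A", 50)
  amp <- (2 / 50) * Mod(sum(exp(2i * pi * (1:49) / 10)))
  expect_equal(oracleScore(s, p), 1 * amp + 0.5 * 1 - 0.3 * 46,
               tolerance = 1e-12)
  expect_lt(oracleScore(s, p), 0)
  expect_error(oracleScore("ACGTACGT", p), "at least 10")
})

test_that("periodic placement scores higher than contiguous placement", {
  # same number of AA dinucleotides, planted every 10 bp vs contiguously
  periodic <- rep("G", 50)
  for (a in seq(1, 41, 10)) periodic[a:(a + 1)] <- "A"
  contiguous <- rep("G", 50)
  contiguous[c(1, 2, 4, 5, 7, 8, 10, 11, 13, 14)] <- "A"
  p <- oracleParams(wPolyA = 0)       # isolate the periodicity term
  sPer <- paste(periodic, collapse = "")
  sCon <- paste(contiguous, collapse = "")
  expect_equal(sum(strsplit(sPer, "")[[1]] == "A"),
               sum(strsplit(sCon, "")[[1]] == "A"))
  expect_gt(oracleScore(sPer, p), oracleScore(sCon, p))
})

test_that("the oracle WW content and stiffness terms are RC-invariant", {
  set.seed(5)
  for (i in 1:50) {
    s <- randomSeq(40)
    rc <- as.character(reverseComplement(Biostrings::DNAString(s)))
    chs <- strsplit(c(s, rc), "")
    expect_equal(DNAbendR:::.polyAPenalty(chs[[1]]),
                 DNAbendR:::.polyAPenalty(chs[[2]]))
    ww <- DNAbendR:::.wwIndicator(c(s, rc))
    expect_equal(mean(ww[1, ]), mean(ww[2, ]))
  }
})

test_that("noise-free libraries give identical labels to identical sequences", {
  lib <- makeLibrary(300, seed = 9, params = oracleParams(noiseSd = 0))
  chars <- as.character(sequences(lib))
  dup <- duplicated(chars) | duplicated(chars, fromLast = TRUE)
  if (any(dup)) {
    for (s in unique(chars[dup]))
      expect_equal(stats::sd(cycLabels(lib)[chars == s]), 0)
  }
  # labels are a deterministic function of the sequence: rebuild from the
  # stored standardization constants
  raw <- oracleScore(chars, lib@meta$params)
  rebuilt <- (raw - lib@meta$labelMean) / lib@meta$labelSd
  expect_equal(cycLabels(lib), rebuilt, tolerance = 1e-12)
})

test_that("library labels are standardized and class structure is present", {
  lib <- makeLibrary(5000, seed = 2)
  lab <- cycLabels(lib)
  expect_equal(mean(lab), 0, tolerance = 1e-12)
  expect_equal(stats::sd(lab), 1, tolerance = 1e-12)
  cls <- lib@meta$class
  expect_setequal(unique(cls), c("random", "periodic", "polyA"))
  # periodic class is more bendable than random by a clear margin
  gap <- mean(lab[cls == "periodic"]) - mean(lab[cls == "random"])
  expect_gt(gap, 0.5)
  # poly(dA:dT) class is the stiffest
  expect_lt(mean(lab[cls == "polyA"]), mean(lab[cls == "random"]))
  expect_error(makeLibrary(10, mix = c(0.5, 0.6, 0.2)), "summing")
})

test_that("generation is bit-identical under a fixed seed", {
  l1 <- makeLibrary(100, seed = 33)
  l2 <- makeLibrary(100, seed = 33)
  expect_identical(as.character(sequences(l1)),
                   as.character(sequences(l2)))
  expect_identical(cycLabels(l1), cycLabels(l2))
  g1 <- makeSyntheticGenome(20000, nElements = 5, tractLengths = c(5, 7),
                            seed = 12)
  g2 <- makeSyntheticGenome(20000, nElements = 5, tractLengths = c(5, 7),
                            seed = 12)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
})

test_that("an unplanted genome has uniform composition", {
  g <- makeSyntheticGenome(1e6, seed = 3)
  comp <- fitMarginal(as.character(g$seq))
  expect_lt(max(abs(comp - 0.25)), 0.01)
  expect_equal(length(g$anchors$dyads), 0L)
})

test_that("planted periodic elements produce a 10-bp periodic WW profile", {
  g <- makeSyntheticGenome(120000, nElements = 100, seed = 8)
  ch <- as.character(g$seq)
  dy <- BiocGenerics::start(g$anchors$dyads)
  frags <- vapply(dy, function(d) substr(ch, d - 50, d + 50), character(1))
  prof <- dinucleotideProfile(frags, c("AA", "AT", "TA", "TT"))
  # autocorrelation of the centered profile: lag 10 must beat lag 5
  ac <- function(lag) {
    x <- prof - mean(prof)
    sum(x[seq_len(length(x) - lag)] * x[-seq_len(lag)])
  }
  expect_gt(ac(10), ac(5) + 0.1 * abs(ac(10)))
})

test_that("planted tracts and motifs are recoverable from the truth tables", {
  pwm <- readJASPAR(syntheticCTCFPath())
  g <- makeSyntheticGenome(200000, tractLengths = rep(c(5, 7, 9), 10),
                           pwm = pwm, nMotifs = 100, seed = 21)
  ch <- as.character(g$seq)
  # every truth tract is found at its planted exact length
  tt <- g$anchors$tracts
  for (len in c(5, 7, 9)) {
    found <- findPolyATracts(ch, len, chrom = "chrS")
    planted <- tt[tt$runEnd - tt$runStart + 1L == len]
    expect_true(all(BiocGenerics::start(planted) %in%
                      BiocGenerics::start(found)))
  }
  # PWM refinement recovers planted motif centers (a vicinity holding two
  # planted sites may legitimately resolve to the stronger neighbour, so
  # a hit is any refined anchor landing on a planted center)
  mt <- g$anchors$motifs
  ref <- pwmRefineSites(ch, mt, pwm, radius = 60L)
  hits <- sum(BiocGenerics::start(ref) %in% BiocGenerics::start(mt))
  expect_gte(hits, 99L)
  # and the large majority resolve to their own vicinity's site
  expect_gte(sum(BiocGenerics::start(ref) == BiocGenerics::start(mt)), 95L)
})

test_that("held-out recovery improves monotonically as label noise falls", {
  rs <- vapply(c(1.0, 0.5, 0.1), function(ns) {
    lib <- makeLibrary(2600, seed = 55, params = oracleParams(noiseSd = ns))
    tr <- lib[1:2200]; va <- lib[2201:2400]; te <- lib[2401:2600]
    m <- trainModel(tr, va, config = tinyConfig(),
                    hyper = trainHyper(batchSize = 128L, maxEpochs = 3L,
                                       patience = 5L), seed = 4)
    pearsonR(predictCScore(m, sequences(te)),
             oracleScore(sequences(te), oracleParams(noiseSd = ns)))
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})
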