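test_that("dinucleotide profiles count class membership per position", {
  p <- dinucleotideProfile(c("AATT", "AAGG"), c("AA", "AT", "TA", "TT"))
  expect_equal(p, c(1.0, 0.5, 0.5))
  # single sequence: 0/1 indicators
  p1 <- dinucleotideProfile("AGAT", c("AA", "AT", "TA", "TT"))
  expect_equal(p1, c(0, 0, 1))
  expect_error(dinucleotideProfile(c("AA", "ACG")), "same length")
})

test_that("WW, SS and mixed dinucleotide classes partition every position", {
  ww <- c("AA", "AT", "TA", "TT")
  ss <- c("GG", "GC", "CG", "CC")
  mixed <- setdiff(as.vector(outer(c("A", "C", "G", "T"),
                                   c("A", "C", "G", "T"), paste0)),
                   c(ww, ss))
  set.seed(31)
  seqs <- randomSeqs(40, 25)
  tot <- dinucleotideProfile(seqs, ww) + dinucleotideProfile(seqs, ss) +
    dinucleotideProfile(seqs, mixed)
  expect_equal(tot, rep(1, 24))
})

test_that("dinucleotide profile agrees with a brute-force counter", {
  set.seed(7)
  for (rep in 1:5) {
    seqs <- randomSeqs(15, 12)
    cls <- sample(as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)), 5)
    brute <- sapply(1:11, function(t)
      mean(vapply(seqs, function(s)
        substr(s, t, t + 1) %in% cls, logical(1))))
    expect_equal(dinucleotideProfile(seqs, cls), brute)
  }
})

test_that("aligned mean profiles average strand-aware offsets", {
  tr <- cScoreTrack("c1", 25:44, as.numeric(1:20))
  # constant track: profile is the constant with full counts
  cst <- cScoreTrack("c1", 25:44, rep(3.5, 20))
  a <- anchorSet("c1", c(30L, 35L))
  p <- alignedMeanProfile(cst, a, flank = 2L)
  expect_equal(p$mean, rep(3.5, 5))
  expect_equal(p$count, rep(2L, 5))
  # one + and one - anchor at the same position: mean of signal and its
  # mirror
  b <- anchorSet("c1", c(30L, 30L), strand = c("+", "-"))
  p2 <- alignedMeanProfile(tr, b, flank = 2L)
  sig <- function(pos) tr@score[match(pos, tr@pos)]
  expected <- vapply(-2:2, function(d)
    mean(c(sig(30 + d), sig(30 - d))), numeric(1))
  expect_equal(p2$mean, expected)
  # edge anchors lose counts, not error
  e <- anchorSet("c1", 26L)
  p3 <- alignedMeanProfile(tr, e, flank = 3L)
  expect_equal(p3$count, c(0L, 0L, rep(1L, 5)))
  expect_true(is.na(p3$mean[1]))
  expect_error(alignedMeanProfile(tr, anchorSet("c1", 500L), flank = 2L),
               "overlaps")
})

test_that("profiles are linear in the signal", {
  set.seed(12)
  tr <- cScoreTrack("c1", 25:124, rnorm(100))
  tr2 <- cScoreTrack("c1", 25:124, 3 * tr@score + 1)
  a <- anchorSet("c1", sample(40:110, 8), strand = sample(c("+", "-"), 8,
                                                          TRUE))
  p1 <- alignedMeanProfile(tr, a, flank = 5L)
  p2 <- alignedMeanProfile(tr2, a, flank = 5L)
  expect_equal(p2$mean, 3 * p1$mean + 1, tolerance = 1e-12)
})

test_that("strand mirroring leaves profiles unchanged", {
  set.seed(44)
  n <- 120
  tr <- cScoreTrack("c1", 25:(24 + n), rnorm(n))
  a <- anchorSet("c1", sample(40:100, 10),
                 strand = sample(c("+", "-"), 10, TRUE))
  # mirror the signal around the track midpoint and flip anchor strands
  lo <- 25L; hi <- 24L + n
  trM <- cScoreTrack("c1", 25:(24 + n), rev(tr@score))
  aM <- anchorSet("c1", lo + hi - BiocGenerics::start(a),
                 strand = ifelse(as.character(BiocGenerics::strand(a)) ==
                                   "+", "-", "+"))
  p1 <- alignedMeanProfile(tr, a, flank = 6L)
  p2 <- alignedMeanProfile(trM, aM, flank = 6L)
  expect_equal(p2$mean, p1$mean, tolerance = 1e-12)
  expect_equal(p2$count, p1$count)
})

test_that("quartile stratification partitions with ties to the lower quartile", {
  a <- anchorSet("c1", 1:8, score = c(10, 20, 30, 40, 50, 60, 70, 80))
  q <- quartileStratify(a)
  expect_equal(vapply(q, length, integer(1)),
               c(Q1 = 2L, Q2 = 2L, Q3 = 2L, Q4 = 2L))
  expect_equal(sum(vapply(q, length, integer(1))), length(a))
  # scores exactly at a boundary stay in the lower quartile
  b <- anchorSet("c1", 1:4, score = c(1, 2, 2, 3))
  qb <- quartileStratify(b)
  expect_equal(unname(vapply(qb, length, integer(1))[2]),
               sum(b$score > quantile(b$score, 0.25) &
                     b$score <= quantile(b$score, 0.5)))
  expect_error(quartileStratify(anchorSet("c1", 1:3)), "score")
})

test_that("poly(dA:dT) tract calls respect exact-length maximality", {
  g <- findPolyATracts("TTAAAAAGG", 5)
  expect_equal(length(g), 1L)
  expect_equal(BiocGenerics::start(g), 5L)       # center of run 3..7
  expect_equal(as.character(BiocGenerics::strand(g)), "+")
  expect_equal(g$runStart, 3L)
  expect_equal(g$runEnd, 7L)
  # a 6-run contains no exact-5 tract
  expect_equal(length(findPolyATracts("AAAAAA", 5)), 0L)
  # alternating AT has no homopolymer run >= 2
  expect_equal(length(findPolyATracts("ATATAT", 2)), 0L)
  # T-runs are called on the minus strand
  gT <- findPolyATracts("GGTTTTTGG", 5)
  expect_equal(as.character(BiocGenerics::strand(gT)), "-")
})

test_that("tract calls match a regex-based enumeration on random sequences", {
  set.seed(3)
  for (len in 1:10) {
    s <- randomSeq(10000)
    got <- findPolyATracts(s, len)
    ref <- integer(0)
    for (base in c("A", "T")) {
      rx <- sprintf("(?<![%s])%s{%d}(?![%s])", base, base, len, base)
      m <- gregexpr(rx, s, perl = TRUE)[[1]]
      if (m[1] != -1) ref <- c(ref, as.integer(m) + (len - 1L) %/% 2L)
    }
    expect_setequal(BiocGenerics::start(got), ref)
  }
})

test_that("PWM refinement recovers planted consensus sites", {
  set.seed(23)
  pwm <- readJASPAR(syntheticCTCFPath())
  cons <- apply(pwm, 2, function(p) c("A", "C", "G", "T")[which.max(p)])
  cons <- paste(cons, collapse = "")
  hits <- 0L
  n <- 100L
  for (i in seq_len(n)) {
    g <- randomSeq(400)
    at <- sample(150:220, 1)
    substr(g, at, at + 18) <- cons
    ref <- pwmRefineSites(g, anchorSet("seq1", 200L), pwm, radius = 199L)
    if (length(ref) == 1L && BiocGenerics::start(ref) == at + 9L &&
        as.character(BiocGenerics::strand(ref)) == "+")
      hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("PWM refinement tie rules: palindromes to '+', uniform to leftmost", {
  pal <- consensusPWM("ACGT")          # reverse complement of ACGT is ACGT
  g <- paste0("GGGGG", "ACGT", "GGGGG")
  ref <- pwmRefineSites(g, anchorSet("seq1", 7L), pal, radius = 6L)
  expect_equal(as.character(BiocGenerics::strand(ref)), "+")
  unif <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  g2 <- randomSeq(30)
  ref2 <- pwmRefineSites(g2, anchorSet("seq1", 15L), unif, radius = 10L)
  expect_equal(BiocGenerics::start(ref2), 5L + 1L)   # leftmost + center
  expect_equal(ref2$score, 0, tolerance = 1e-9)
  # region shorter than the motif is skipped with a warning
  wide <- consensusPWM(strrep("A", 25))
  expect_warning(
    out <- pwmRefineSites(randomSeq(40), anchorSet("seq1", 5L), wide,
                          radius = 2L),
    "skipped")
  expect_equal(length(out), 0L)
})

test_that("anchor BED round trip crosses the 0-based boundary correctly", {
  a <- anchorSet("c1", c(10L, 25L), strand = c("+", "-"),
                 score = c(1.5, -2))
  f <- tempfile(fileext = ".bed")
  writeAnchorsBED(a, f)
  df <- read.table(f)
  expect_equal(df$V2, c(9, 24))          # BED start = pos - 1
  expect_equal(df$V3, c(10, 25))
  b <- readAnchorsBED(f)
  expect_equal(BiocGenerics::start(b), BiocGenerics::start(a))
  expect_equal(as.character(BiocGenerics::strand(b)),
               as.character(BiocGenerics::strand(a)))
  expect_equal(b$score, a$score)
})

test_that("z-scoring a track standardizes its scores", {
  tr <- cScoreTrack("c1", 25:44, rnorm(20, 5, 2))
  z <- zscoreTrack(tr)
  expect_equal(mean(trackScores(z)), 0, tolerance = 1e-12)
  expect_equal(stats::sd(trackScores(z)), 1, tolerance = 1e-12)
  expect_error(zscoreTrack(cScoreTrack("c1", 25:26, c(1, 1))), "constant")
})
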