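# Synthetic loop-seq-like data with a documented ground-truth bendability
# oracle.  The oracle is a test scaffold emulating the reported sequence
# determinants of cyclizability -- phase-coherent 10-bp-periodic
# AA/AT/TA/TT occupancy and poly(dA:dT) stiffness -- not a claim about
# true DNA mechanics.  Its formula is frozen so downstream recovery
# experiments are stable.

.WW <- c("AA", "AT", "TA", "TT")

#' Parameters of the synthetic bendability oracle
#'
#' The noiseless oracle score of a sequence s of length L is
#' `w_per * A(s) + w_ww * f_WW(s) - w_polyA * P(s)`, where
#' `f_WW` is the fraction of dinucleotide positions carrying an
#' AA/AT/TA/TT 2-mer, `A(s) = (2/L) * |sum_t I_WW(t) exp(2*pi*i*t/period)|`
#' is the phase-coherent amplitude of the 10-bp periodic WW signal, and
#' `P(s)` sums `max(0, runLength - 4)` over maximal single-base A-runs and
#' T-runs (poly(dA:dT) stiffness penalty).
#'
#' @param wPer weight of the periodicity amplitude (default 1.0).
#' @param wWw weight of the WW-dinucleotide content (default 0.5).
#' @param wPolyA penalty weight per poly(dA:dT) base beyond run length 4
#'   (default 0.3).
#' @param period period in bp (default 10; 10.5 is also meaningful).
#' @param noiseSd standard deviation of the Gaussian measurement noise
#'   added to library labels (default 0.3).
#' @return parameter list.
#' @export
oracleParams <- function(wPer = 1.0, wWw = 0.5, wPolyA = 0.3,
                         period = 10.0, noiseSd = 0.3) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (period <= 0) stop("period must be positive")
  list(wPer = wPer, wWw = wWw, wPolyA = wPolyA, period = period,
       noiseSd = noiseSd)
}

# WW indicator over dinucleotide start positions 1..L-1
.wwIndicator <- function(chars) {
  n <- nchar(chars)
  stopifnot(length(unique(n)) == 1L)
  L <- n[1L]
  vapply(seq_len(L - 1L),
         function(t) substr(chars, t, t + 1L) %in% .WW,
         logical(length(chars)))
}

# poly(dA:dT) penalty of one character vector sequence
.polyAPenalty <- function(ch) {
  r <- rle(ch)
  keep <- r$values %in% c("A", "T")
  sum(pmax(0L, r$lengths[keep] - 4L))
}

#' Noiseless oracle bendability score
#'
#' @param seqs sequences of equal length >= 10 (`DNAStringSet` or
#'   character).
#' @param params parameters from [oracleParams()].
#' @return numeric vector of deterministic oracle scores.
#' @export
oracleScore <- function(seqs, params = oracleParams()) {
  chars <- .asDNAChar(validateDNA(seqs))
  L <- unique(nchar(chars))
  if (length(L) != 1L) stop("sequences must all have the same length")
  if (L < 10L) stop("sequences must be at least 10 bp")
  ww <- .wwIndicator(chars)                      # n x (L-1)
  if (is.vector(ww)) ww <- matrix(ww, nrow = length(chars))
  fww <- rowMeans(ww)
  ph <- exp(2i * pi * seq_len(L - 1L) / params$period)
  amp <- (2 / L) * Mod(ww %*% ph)
  pen <- vapply(strsplit(chars, "", fixed = TRUE), .polyAPenalty,
                numeric(1))
  as.numeric(params$wPer * amp + params$wWw * fww - params$wPolyA * pen)
}

# class generators (integer base matrices, 1..4 = A,C,G,T)
.genRandom <- function(n, L) matrix(sample.int(4L, n * L, TRUE), n, L)

# periodic class: random background, then 5-bp W (A/T) patterns planted
# at period-spaced offsets from a random per-sequence global phase (phase
# diversity across sequences, phase coherence within each).  Patterns
# avoid pure single-base runs longer than 2 so the periodic class gains
# bendability without incurring the poly(dA:dT) stiffness penalty.
.PERIODIC_PATTERNS <- rbind(
  c(1L, 1L, 4L, 4L, 1L, 1L), c(4L, 4L, 1L, 1L, 4L, 4L),
  c(1L, 4L, 4L, 1L, 1L, 4L), c(4L, 1L, 1L, 4L, 4L, 1L),
  c(1L, 4L, 1L, 4L, 1L, 4L), c(4L, 1L, 4L, 1L, 4L, 1L))

.genPeriodic <- function(n, L, period) {
  bm <- .genRandom(n, L)
  pw <- ncol(.PERIODIC_PATTERNS)
  for (i in seq_len(n)) {
    phase <- sample.int(round(period), 1L)
    # include a clipped plant upstream of the phase so coverage does not
    # depend on the drawn phase
    at <- round(seq(phase - round(period), L - pw + 1L, by = period))
    for (a in at) {
      pat <- .PERIODIC_PATTERNS[sample.int(6L, 1L), ]
      lo <- max(a, 1L)
      if (lo > a + pw - 1L) next
      bm[i, lo:(a + pw - 1L)] <- pat[(lo - a + 1L):pw]
      # S (G/C) guard after the plant: a background W base there would
      # sit half a period out of phase and cancel amplitude
      if (a + pw <= L) bm[i, a + pw] <- sample(2:3, 1L)
    }
  }
  bm
}

# polyA class: random background with 1-2 pure A or T tracts of length
# 5-9
.genPolyA <- function(n, L) {
  bm <- .genRandom(n, L)
  for (i in seq_len(n)) {
    for (k in seq_len(sample(1:2, 1L))) {
      len <- sample(5:9, 1L)
      a <- sample.int(L - len + 1L, 1L)
      bm[i, a:(a + len - 1L)] <- sample(c(1L, 4L), 1L)
    }
  }
  bm
}

#' Generate a synthetic loop-seq-like sequence library
#'
#' Sequences are drawn from a mixture of three classes: unstructured
#' random sequences, a periodic-enriched class with W (A/T) runs planted
#' at 10-bp-spaced offsets from a random global phase per sequence
#' (emulating the phase diversity of highly bendable fragments), and a
#' poly(dA:dT)-enriched class carrying stiff tracts of length 5-9.
#' Labels are `oracleScore + N(0, noiseSd)`, standardized to sample mean
#' 0 and unit variance; the class assignment, the noiseless oracle values
#' and the generation parameters are embedded in the library metadata.
#'
#' @param n number of sequences.
#' @param L sequence length in bp (default 50).
#' @param mix class fractions (random, periodic, polyA), summing to 1.
#' @param params oracle parameters, [oracleParams()].
#' @param seed integer seed; generation is a pure function of the
#'   arguments and the seed.
#' @param name library name.
#' @return a [SequenceLibrary-class] with standardized labels.
#' @export
makeLibrary <- function(n, L = 50L,
                        mix = c(random = 0.34, periodic = 0.33,
                                polyA = 0.33),
                        params = oracleParams(), seed = 1L,
                        name = "synthetic") {
  mix <- as.numeric(mix)
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
    stop("mix must be 3 non-negative fractions summing to 1")
  set.seed(seed)
  nCl <- c(floor(mix[1L] * n), floor(mix[2L] * n), 0L)
  nCl[3L] <- n - sum(nCl[1:2])
  bm <- rbind(
    if (nCl[1L]) .genRandom(nCl[1L], L),
    if (nCl[2L]) .genPeriodic(nCl[2L], L, params$period),
    if (nCl[3L]) .genPolyA(nCl[3L], L))
  cls <- rep(c("random", "periodic", "polyA"), nCl)
  ord <- sample.int(n)                      # shuffle class blocks
  bm <- bm[ord, , drop = FALSE]; cls <- cls[ord]
  chars <- .collapseRows(bm)
  truth <- oracleScore(chars, params)
  labels <- truth + stats::rnorm(n, 0, params$noiseSd)
  lm_ <- mean(labels); ls_ <- stats::sd(labels)
  if (ls_ == 0) stop("degenerate library: constant labels")
  sequenceLibrary(chars, (labels - lm_) / ls_, name = name,
                  meta = list(class = cls, oracle = truth,
                              params = params, seed = seed,
                              labelMean = lm_, labelSd = ls_))
}

#' Generate a synthetic genome with planted features and truth anchors
#'
#' A uniform-background chromosome carrying (optionally) nucleosome-like
#' periodic elements (W dinucleotides planted every `period` bp across a
#' 101-bp footprint, phase-aligned at the element center), poly(dA:dT)
#' tracts of stated exact lengths, and PWM motif instances with random
#' strand.  Features are placed greedily at random non-overlapping
#' positions; an overcrowded plan is an error.  Truth anchor tables
#' (dyad-like centers, tract centers, motif centers with strand) are
#' returned for downstream profile tests.
#'
#' @param length chromosome length in bp.
#' @param nElements number of nucleosome-like periodic elements.
#' @param tractLengths integer vector of exact poly(dA:dT) tract lengths
#'   to plant (one tract per entry).
#' @param pwm optional 4 x W probability matrix; `nMotifs` instances are
#'   planted.
#' @param nMotifs number of motif instances.
#' @param period spacing of the planted W dinucleotides in bp.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return list with `seq` (a `DNAString`), and `anchors`: a list of
#'   width-1 `GRanges` truth tables (`dyads`, `tracts`, `motifs`).
#' @export
makeSyntheticGenome <- function(length, nElements = 0L,
                                tractLengths = integer(),
                                pwm = NULL, nMotifs = 0L, period = 10L,
                                seed = 1L, chrom = "chrS") {
  set.seed(seed)
  L <- as.integer(length)
  ch <- sample(.BASES, L, replace = TRUE)
  occupied <- logical(L)
  placeOne <- function(fw) {
    # random non-overlapping placement of a footprint of width fw;
    # returns the start or errors when impossible
    for (try in seq_len(2000L)) {
      a <- sample.int(L - fw + 1L, 1L)
      if (!any(occupied[a:(a + fw - 1L)])) {
        occupied[a:(a + fw - 1L)] <<- TRUE
        return(a)
      }
    }
    stop("placement error: overcrowded plan, features do not fit")
  }
  half <- 50L
  dyads <- integer(nElements)
  if (nElements > 0L) {
    for (e in seq_len(nElements)) {
      a <- placeOne(2L * half + 1L)
      ctr <- a + half
      dyads[e] <- ctr
      for (off in seq(-half, half - 1L, by = period)) {
        p <- ctr + off
        ch[p:(p + 1L)] <- sample(c("A", "T"), 2L, replace = TRUE)
      }
    }
  }
  tracts <- integer(0); tractStrand <- character(0)
  tractFrom <- integer(0); tractTo <- integer(0)
  for (tl in tractLengths) {
    a <- placeOne(tl + 2L)                 # 1-bp margin keeps runs exact
    base <- sample(c("A", "T"), 1L)
    ch[a] <- if (base == "A") "G" else "C"
    ch[a + tl + 1L] <- if (base == "A") "G" else "C"
    ch[(a + 1L):(a + tl)] <- base
    tracts <- c(tracts, a + 1L + (tl - 1L) %/% 2L)
    tractStrand <- c(tractStrand, if (base == "A") "+" else "-")
    tractFrom <- c(tractFrom, a + 1L); tractTo <- c(tractTo, a + tl)
  }
  motifs <- integer(0); motifStrand <- character(0)
  if (!is.null(pwm) && nMotifs > 0L) {
    pwm <- .validPWM(pwm)
    W <- ncol(pwm)
    for (k in seq_len(nMotifs)) {
      a <- placeOne(W)
      inst <- .BASES[vapply(seq_len(W), function(j)
        .sampleBase(matrix(pwm[, j], 1L, 4L)), integer(1))]
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
      ch[a:(a + W - 1L)] <- inst
      motifs <- c(motifs, a + (W - 1L) %/% 2L)
      motifStrand <- c(motifStrand, strand)
    }
  }
  tractGR <- anchorSet(chrom, tracts, tractStrand)
  if (length(tractGR)) {
    S4Vectors::mcols(tractGR)$runStart <- tractFrom
    S4Vectors::mcols(tractGR)$runEnd <- tractTo
  }
  list(seq = Biostrings::DNAString(paste(ch, collapse = "")),
       anchors = list(
         dyads = anchorSet(chrom, sort(dyads)),
         tracts = tractGR,
         motifs = anchorSet(chrom, motifs, motifStrand)))
}
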