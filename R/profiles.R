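# Feature-anchored signal analytics: dinucleotide-class frequency
# profiles, strand-aware mean-signal profiles around anchors, quartile
# stratification, poly(dA:dT) tract detection, PWM refinement of peak
# regions.

#' Construct a feature anchor set
#'
#' Anchors (nucleosome dyads, TSSs, TF binding-site centers, ...) are
#' represented as width-1 `GRanges` with strand and an optional score.
#'
#' @param chrom character chromosome name(s).
#' @param pos integer 1-based positions.
#' @param strand "+" or "-" per anchor (default "+").
#' @param score optional numeric score (e.g. NCP or motif score).
#' @return a `GRanges` of width-1 anchors.
#' @export
anchorSet <- function(chrom, pos, strand = "+", score = NULL) {
  if (length(pos) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(score)) S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(as.integer(pos),
                                                width = rep(1L,
                                                            length(pos))),
                               strand = strand)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  gr
}

#' Read / write anchors as BED6
#'
#' BED is 0-based half-open; conversion to the internal 1-based width-1
#' anchors happens at this boundary (via rtracklayer).  The BED score
#' column carries the anchor score.
#'
#' @param path file path.
#' @return `readAnchorsBED` returns a `GRanges` of width-1 anchors.
#' @export
readAnchorsBED <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(BiocGenerics::width(gr) != 1L))
    gr <- GenomicRanges::resize(gr, width = 1L, fix = "center")
  gr
}

#' @rdname readAnchorsBED
#' @param anchors a `GRanges` of width-1 anchors.
#' @export
writeAnchorsBED <- function(anchors, path) {
  if (is.null(anchors$score)) anchors$score <- 0
  if (is.null(anchors$name)) anchors$name <- "."
  rtracklayer::export(anchors, path, format = "BED")
  invisible(path)
}

#' Positional dinucleotide-class frequency profile
#'
#' For aligned equal-length sequences, the fraction of sequences whose
#' 2-mer starting at each position belongs to the given class (e.g. the
#' bendability-associated class AA/AT/TA/TT, or its GC-class
#' counterpart).
#'
#' @param seqs equal-length sequences (`DNAStringSet` or character).
#' @param motifClass character vector of 2-mers, e.g.
#'   `c("AA","AT","TA","TT")`.
#' @return numeric vector of length L-1: the class frequency at positions
#'   1..L-1.
#' @export
dinucleotideProfile <- function(seqs,
                                motifClass = c("AA", "AT", "TA", "TT")) {
  chars <- .asDNAChar(validateDNA(seqs))
  L <- unique(nchar(chars))
  if (length(L) != 1L) stop("sequences must all have the same length")
  if (L < 2L) stop("sequences must be at least 2 bp")
  motifClass <- toupper(motifClass)
  out <- numeric(L - 1L)
  for (t in seq_len(L - 1L))
    out[t] <- mean(substr(chars, t, t + 1L) %in% motifClass)
  out
}

# per-chromosome position -> score lookup from a CScoreTrack or a GRanges
# signal
.signalLookup <- function(signal) {
  if (is(signal, "CScoreTrack")) {
    lk <- list()
    lk[[signal@chrom]] <- list(pos = signal@pos, score = signal@score)
    return(lk)
  }
  if (is(signal, "GRanges")) {
    if (is.null(signal$score)) stop("signal GRanges needs a score column")
    sp <- split(seq_along(signal),
                as.character(GenomeInfoDb::seqnames(signal)))
    return(lapply(sp, function(i)
      list(pos = BiocGenerics::start(signal)[i], score = signal$score[i])))
  }
  stop("signal must be a CScoreTrack or a GRanges with scores")
}

#' Mean signal profile aligned at anchors
#'
#' For each offset d in `-flank..flank`, the mean of the signal at
#' `position + d` over plus-strand anchors and `position - d` over
#' minus-strand anchors.  Positions missing from the signal (track gaps,
#' chromosome edges) are excluded from both the mean and the reported
#' count, so edge attrition is visible rather than silently zero-filled.
#'
#' @param signal a [CScoreTrack-class] or a `GRanges` with a `score`
#'   column (any per-bp signal).
#' @param anchors width-1 `GRanges` anchors (see [anchorSet()]).
#' @param flank half-width F of the profile in bp.
#' @return data.frame with columns `offset` (-F..F), `mean`, `count`.
#' @export
alignedMeanProfile <- function(signal, anchors, flank) {
  if (flank < 0) stop("flank must be >= 0")
  lk <- .signalLookup(signal)
  chroms <- as.character(GenomeInfoDb::seqnames(anchors))
  pos <- BiocGenerics::start(anchors)
  str <- as.character(BiocGenerics::strand(anchors))
  str[str == "*"] <- "+"
  offs <- seq.int(-flank, flank)
  sm <- numeric(length(offs)); ct <- integer(length(offs))
  for (ch in unique(chroms)) {
    if (is.null(lk[[ch]])) next
    sel <- chroms == ch
    p <- pos[sel]; sgn <- ifelse(str[sel] == "+", 1L, -1L)
    tp <- lk[[ch]]$pos; ts <- lk[[ch]]$score
    for (i in seq_along(offs)) {
      tgt <- p + sgn * offs[i]
      hit <- match(tgt, tp)
      ok <- !is.na(hit)
      ct[i] <- ct[i] + sum(ok)
      sm[i] <- sm[i] + sum(ts[hit[ok]])
    }
  }
  if (sum(ct) == 0L) stop("no anchor position overlaps the signal")
  data.frame(offset = offs, mean = ifelse(ct > 0, sm / ct, NA_real_),
             count = ct)
}

#' Stratify anchors into score quartiles
#'
#' Partition by the empirical 25/50/75 percentiles (linear-interpolation
#' quantiles); Q1 holds the lowest scores, Q4 the highest.  Scores tied
#' with a boundary are assigned to the lower quartile.
#'
#' @param anchors `GRanges` anchors, all with scores.
#' @return named list of four `GRanges` (Q1..Q4).
#' @export
quartileStratify <- function(anchors) {
  s <- anchors$score
  if (is.null(s) || anyNA(s)) stop("all anchors must carry a score")
  qs <- stats::quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  grp <- 1L + (s > qs[1L]) + (s > qs[2L]) + (s > qs[3L])
  stats::setNames(lapply(1:4, function(g) anchors[grp == g]),
                  paste0("Q", 1:4))
}

#' Find poly(dA:dT) tracts of an exact length
#'
#' Maximal runs consisting entirely of A, or entirely of T, whose length
#' is exactly `exactLen` (a run of 6 As contains no length-5 tract: runs
#' are maximal).  The anchor is the run center; for even lengths, the
#' base left of center.  A-runs are reported on "+", T-runs on "-".
#'
#' @param seq a single sequence (`DNAString` or character).
#' @param exactLen required run length in bp (>= 1).
#' @param chrom chromosome name recorded on the anchors.
#' @return width-1 `GRanges` anchors with metadata columns `runStart`,
#'   `runEnd`.
#' @export
findPolyATracts <- function(seq, exactLen, chrom = "seq1") {
  if (exactLen < 1L) stop("exactLen must be >= 1")
  s <- .asDNAChar(validateDNA(seq))
  if (length(s) != 1L) stop("one sequence at a time")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("A", "T") & r$lengths == exactLen
  if (!any(keep))
    return(anchorSet(character(), integer(), character()))
  starts <- starts[keep]; ends <- ends[keep]
  centers <- starts + (exactLen - 1L) %/% 2L   # left-of-center when even
  gr <- anchorSet(chrom, centers,
                  strand = ifelse(r$values[keep] == "A", "+", "-"))
  S4Vectors::mcols(gr)$runStart <- starts
  S4Vectors::mcols(gr)$runEnd <- ends
  gr
}

#' Refine anchor positions by PWM scanning
#'
#' For each region (anchor +/- `radius`), both strands are scanned with
#' the PWM log-odds; the maximum-scoring motif position (its left-of-
#' center base) becomes the refined anchor, with the hit score and
#' strand.  Ties break to the leftmost position, then to "+".  Regions
#' shorter than the motif are skipped with a warning.
#'
#' @param genome a named list of sequences, a `DNAStringSet`, or a single
#'   sequence (then all anchors must be on its chromosome).
#' @param regions width-1 `GRanges` anchors marking region centers.
#' @param pwm 4 x W probability matrix.
#' @param radius vicinity half-width in bp around each region center.
#' @param background,pseudocount see [pwmLogOdds()].
#' @return width-1 `GRanges` of refined anchors with `score` (best
#'   log-odds) metadata.
#' @export
pwmRefineSites <- function(genome, regions, pwm, radius = 200L,
                           background = 0.25, pseudocount = 1e-3) {
  pwm <- .validPWM(pwm)
  lo <- pwmLogOdds(pwm, background, pseudocount)
  W <- ncol(pwm)
  if (is(genome, "DNAString") || (is.character(genome) &&
                                  length(genome) == 1L &&
                                  is.null(names(genome)))) {
    genome <- stats::setNames(list(.asDNAChar(genome)),
                              as.character(GenomeInfoDb::seqnames(
                                regions))[1])
  } else {
    nm <- names(genome)
    genome <- stats::setNames(as.list(.asDNAChar(genome)), nm)
  }
  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  pos <- BiocGenerics::start(regions)
  outChrom <- character(); outPos <- integer(); outStrand <- character()
  outScore <- numeric()
  for (i in seq_along(regions)) {
    gseq <- genome[[chroms[i]]]
    if (is.null(gseq)) stop("no genome sequence for ", chroms[i])
    lo_ <- max(1L, pos[i] - radius)
    hi_ <- min(nchar(gseq), pos[i] + radius)
    frag <- substr(gseq, lo_, hi_)
    if (nchar(frag) < W) {
      warning(sprintf("region %d shorter than the motif; skipped", i))
      next
    }
    best <- .scanPWMBest(frag, lo)
    if (is.null(best)) next
    outChrom <- c(outChrom, chroms[i])
    outPos <- c(outPos, lo_ + best$pos - 1L + (W - 1L) %/% 2L)
    outStrand <- c(outStrand, best$strand)
    outScore <- c(outScore, best$score)
  }
  anchorSet(outChrom, outPos, outStrand, outScore)
}

#' Z-score a signal track
#'
#' Standardizes track scores to mean 0 and unit variance, the
#' normalization applied to occupancy/NCP signals before profiling.
#'
#' @param track a [CScoreTrack-class].
#' @return the track with standardized scores.
#' @export
zscoreTrack <- function(track) {
  s <- stats::sd(track@score)
  if (!is.finite(s) || s == 0) stop("constant signal cannot be z-scored")
  cScoreTrack(track@chrom, track@pos,
              (track@score - mean(track@score)) / s, track@windowWidth)
}
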