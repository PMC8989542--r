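#' Sliding-window C-score track of a long sequence
#'
#' Scores every 50-bp window at 1-bp steps and anchors each score at the
#' window center (`start + 24`): an N-free sequence of length L yields
#' L - 49 scores at centers `25 .. L - 25`.  Windows containing an N are
#' skipped and leave gaps in the track.  Windows are evaluated in batches;
#' the batch size must not (and does not) change the result.
#'
#' @param model a trained [IRLSTMModel-class].
#' @param seq a `DNAString`/character sequence of length >= 50.
#' @param chrom name recorded on the track.
#' @param batchSize number of windows per evaluation batch.
#' @param ... unused.
#' @return a [CScoreTrack-class].
#' @rdname predictTrack
#' @export
setMethod("predictTrack", "IRLSTMModel",
  function(model, seq, chrom = "seq1", batchSize = 256L, ...) {
    s <- .asDNAChar(validateDNA(seq))
    if (length(s) != 1L) stop("predictTrack expects one sequence")
    L <- nchar(s)
    w <- model@config$inputLength
    if (L < w)
      stop(sprintf("sequence length %d < window width %d", L, w))
    M <- oneHotEncode(s)
    isN <- strsplit(s, "", fixed = TRUE)[[1L]] == "N"
    starts <- seq_len(L - w + 1L)
    # windows overlapping any N are skipped (no score is fabricated)
    if (any(isN)) {
      ncum <- cumsum(isN)
      nIn <- ncum[starts + w - 1L] - c(0L, ncum)[starts]
      starts <- starts[nIn == 0L]
    }
    if (length(starts) == 0L)
      return(cScoreTrack(chrom, integer(), numeric(), w))
    centers <- starts + (w %/% 2L - 1L)
    scores <- numeric(length(starts))
    i <- 1L
    while (i <= length(starts)) {
      j <- min(length(starts), i + batchSize - 1L)
      take <- starts[i:j]
      X <- array(0, c(w, 4L, length(take)))
      for (q in seq_along(take))
        X[, , q] <- M[take[q]:(take[q] + w - 1L), ]
      Xrc <- X[rev(seq_len(w)), c(4L, 3L, 2L, 1L), , drop = FALSE]
      n <- length(take)
      both <- array(0, c(w, 4L, 2L * n))
      both[, , seq_len(n)] <- X
      both[, , n + seq_len(n)] <- Xrc
      out <- nnPredict(model@params, model@bnStats, model@config, both)
      raw <- (out[seq_len(n)] + out[n + seq_len(n)]) / 2
      scores[i:j] <- model@detrend[1L] + model@detrend[2L] * raw
      i <- j + 1L
    }
    cScoreTrack(chrom, centers, scores, w)
  })

#' Mean C-score per sequence over all sliding windows
#'
#' For each input sequence, the arithmetic mean of its window C-scores
#' (e.g. a 90-bp sequence averages the 41 windows centered at 25..65).
#'
#' @param model a trained [IRLSTMModel-class].
#' @param seqs `DNAStringSet` or character vector, each of length >= 50.
#' @return numeric vector, one mean per sequence.
#' @export
meanLibraryCScore <- function(model, seqs) {
  chars <- .asDNAChar(validateDNA(seqs))
  vapply(seq_along(chars), function(i) {
    tr <- predictTrack(model, chars[i], chrom = sprintf("seq%d", i))
    if (length(tr) == 0L) return(NA_real_)
    mean(tr@score)
  }, numeric(1))
}

#' Convert a CScoreTrack to GRanges
#'
#' One width-1 range per scored center position (1-based), with a `score`
#' metadata column; the explicit boundary where the internal 1-based
#' coordinates meet interval formats.
#'
#' @param track a [CScoreTrack-class].
#' @param seqLength optional sequence length, recorded as seqlengths.
#' @return a [GenomicRanges::GRanges].
#' @export
trackToGRanges <- function(track, seqLength = NA) {
  gr <- GenomicRanges::GRanges(
    seqnames = track@chrom,
    ranges = IRanges::IRanges(start = track@pos, width = 1L),
    score = track@score)
  if (!is.na(seqLength))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(as.integer(seqLength),
                                                    track@chrom)
  gr
}

#' Write a C-score track as WIG
#'
#' Fixed-step blocks (step 1) over contiguous runs of centers; gaps from
#' skipped N windows break blocks.  A write-then-read round trip
#' reproduces positions and scores.
#'
#' @param track a [CScoreTrack-class].
#' @param path output path (conventionally `.wig`).
#' @return `path`, invisibly.
#' @export
writeWig <- function(track, path) {
  if (length(track@pos) && is.unsorted(track@pos, strictly = TRUE))
    stop("unsorted track positions")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(track@pos)) {
    # break fixedStep blocks wherever consecutive centers are not adjacent
    brk <- c(0L, which(diff(track@pos) != 1L), length(track@pos))
    for (b in seq_len(length(brk) - 1L)) {
      i <- (brk[b] + 1L):brk[b + 1L]
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                         track@chrom, track@pos[i[1L]]), con)
      writeLines(sprintf("%.6f", track@score[i]), con)
    }
  }
  invisible(path)
}

#' Write a C-score track as bedGraph
#'
#' Each 1-based center position p becomes the 0-based half-open interval
#' `[p - 1, p)`.
#'
#' @param track a [CScoreTrack-class].
#' @param path output path (conventionally `.bedgraph`).
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  if (length(track@pos) && is.unsorted(track@pos, strictly = TRUE))
    stop("unsorted track positions")
  rtracklayer::export(trackToGRanges(track), path, format = "bedGraph")
  invisible(path)
}

#' Write a C-score track as TSV
#'
#' Columns: chrom, position (1-based center), score.
#'
#' @param track a [CScoreTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrackTSV <- function(track, path) {
  utils::write.table(
    data.frame(chrom = track@chrom, position = track@pos,
               score = track@score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a track written by [writeWig()] or [writeBedGraph()]
#'
#' @param path a `.wig` or `.bedgraph` file.
#' @param windowWidth window width to record on the track.
#' @return a [CScoreTrack-class].
#' @export
readTrack <- function(path, windowWidth = 50L) {
  gr <- rtracklayer::import(path)
  if (length(gr) && any(BiocGenerics::width(gr) != 1L))
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                 IRanges::IRanges(BiocGenerics::end(gr),
                                                  width = 1L),
                                 score = gr$score)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))[1]
  if (length(gr) == 0L) chrom <- "seq1"
  o <- order(BiocGenerics::start(gr))
  cScoreTrack(chrom, BiocGenerics::start(gr)[o], gr$score[o], windowWidth)
}
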