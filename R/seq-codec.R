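#' @title Sequence representation and encoding
#'
#' @description Helpers shared by the whole package: alphabet validation,
#' one-hot encoding with the fixed channel order (A, C, G, T), sliding
#' 50-bp windows under the center-anchored coordinate convention, and
#' FASTA input.
#'
#' @details Coordinates are 1-based inclusive throughout.  A window of
#' width 50 starting at position 1 is anchored at its 25th base, position
#' 25; equivalently `center = start + 24`.
#' @name seq_codec
NULL

.BASES <- c("A", "C", "G", "T")

#' Validate a DNA sequence over the A/C/G/T/N alphabet
#'
#' Lowercase (soft-masked) input is accepted and folded to uppercase by
#' the underlying `DNAStringSet` constructor; ambiguity codes other than N
#' are rejected.
#'
#' @param x a `DNAString`, `DNAStringSet`, or character vector.
#' @return invisibly, the input as a `DNAStringSet`.
#' @export
validateDNA <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (!is(x, "DNAStringSet"))
    stop("expected a DNAString(Set) or character vector")
  af <- Biostrings::alphabetFrequency(x)
  ok <- c(.BASES, "N")
  bad <- rowSums(af[, !(colnames(af) %in% ok), drop = FALSE])
  if (any(bad > 0))
    stop("invalid sequence: characters outside {A,C,G,T,N} in record(s) ",
         paste(utils::head(which(bad > 0), 5), collapse = ", "))
  invisible(x)
}

.asDNAChar <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    return(toupper(as.character(seq)))
  toupper(as.character(seq))
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as an L x 4 matrix with channel order (A, C, G, T):
#' each unambiguous base becomes a unit row; an N becomes the uniform row
#' (0.25, 0.25, 0.25, 0.25), so every row sums to 1.
#'
#' @param seq a `DNAString` or single character string over {A,C,G,T,N}.
#' @return numeric matrix with L rows and columns named A, C, G, T.
#' @examples
#' oneHotEncode("ACGT")   # the 4 x 4 identity matrix
#' @export
oneHotEncode <- function(seq) {
  s <- .asDNAChar(seq)
  if (length(s) != 1L) stop("encode one sequence at a time")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  if (L < 1L) stop("empty sequence")
  idx <- match(ch, .BASES)
  if (any(is.na(idx) & ch != "N"))
    stop("invalid character(s): ",
         paste(unique(ch[is.na(idx) & ch != "N"]), collapse = ", "))
  m <- matrix(0, L, 4L, dimnames = list(NULL, .BASES))
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1
  if (any(!hit)) m[!hit, ] <- 0.25
  m
}

#' Decode a one-hot matrix back to sequence
#'
#' Argmax decoding; uniform (N) rows decode to "N".
#'
#' @param m matrix from [oneHotEncode()].
#' @return character string.
#' @export
oneHotDecode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  ch <- .BASES[max.col(m, ties.method = "first")]
  ch[abs(m[, 1L] - 0.25) < 1e-12 & abs(m[, 2L] - 0.25) < 1e-12] <- "N"
  paste(ch, collapse = "")
}

# reverse-complement a one-hot matrix without re-encoding: reverse the
# position axis and swap channels A<->T, C<->G
.oneHotRC <- function(m) {
  r <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(r) <- .BASES
  r
}

#' Sliding 50-bp windows over a sequence
#'
#' Enumerates all width-`width` windows at the given step, with the
#' center-anchored convention `center = start + 24` (for width 50): the
#' score of the window `[1, 50]` is reported at position 25.
#'
#' @param seqLength sequence length in bp (or a sequence, whose length is
#'   taken).
#' @param width window width in bp (default 50).
#' @param step step size in bp (default 1).
#' @return an [IRanges::IRanges] of windows with a metadata column
#'   `center`.
#' @examples
#' w <- seqWindows(90)     # 41 windows, centers 25..65
#' range(S4Vectors::mcols(w)$center)
#' @export
seqWindows <- function(seqLength, width = 50L, step = 1L) {
  if (is(seqLength, "DNAString") || is(seqLength, "DNAStringSet") ||
      is.character(seqLength))
    seqLength <- nchar(.asDNAChar(seqLength))[1L]
  L <- as.integer(seqLength)
  width <- as.integer(width); step <- as.integer(step)
  if (L < width)
    stop(sprintf("sequence length %d is shorter than the window width %d",
                 L, width))
  starts <- seq.int(1L, L - width + 1L, by = step)
  w <- IRanges::IRanges(start = starts, width = width)
  S4Vectors::mcols(w)$center <- starts + (width %/% 2L - 1L)
  w
}

#' Read DNA sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA; soft-masked lowercase is folded to
#' uppercase; only A/C/G/T/N are accepted.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet` named by record headers.
#' @export
readFastaDNA <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  if (any(width(seqs) == 0L))
    stop("FASTA record(s) with empty body: ",
         paste(names(seqs)[width(seqs) == 0L], collapse = ", "))
  validateDNA(seqs)
  seqs
}
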