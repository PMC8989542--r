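# Position weight matrices: JASPAR text input, log-odds scoring, strand-
# aware scanning.

.validPWM <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L)
    stop("PWM must be a 4 x W matrix with rows A, C, G, T")
  if (any(pwm < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(pwm)
  if (any(cs <= 0)) stop("PWM column with zero mass")
  pwm <- sweep(pwm, 2L, cs, "/")       # counts -> probabilities
  rownames(pwm) <- .BASES
  pwm
}

#' Read a JASPAR-format PWM
#'
#' Accepts the JASPAR text matrix format: an optional `>ID name` header
#' followed by four rows, either bare numbers or of the form
#' `A [ 87 167 ... ]`.  Count matrices are column-normalized to
#' probabilities on load.
#'
#' @param path path to a JASPAR matrix file.
#' @return a 4 x W probability matrix with rows A, C, G, T, each column
#'   summing to 1.
#' @export
readJASPAR <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln[nzchar(trimws(ln))])
  ln <- ln[!startsWith(ln, ">")]
  if (length(ln) != 4L)
    stop("expected 4 matrix rows in JASPAR file, found ", length(ln))
  rows <- lapply(ln, function(l) {
    l <- sub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged JASPAR matrix rows")
  m <- do.call(rbind, rows)
  # row order: honour leading base letters if present, else assume ACGT
  lead <- toupper(substr(ln, 1L, 1L))
  if (all(sort(lead) == .BASES)) m <- m[match(.BASES, lead), , drop = FALSE]
  .validPWM(m)
}

#' Log-odds score matrix of a PWM
#'
#' Log2 ratio of motif probability to a uniform 0.25 background, with a
#' small pseudocount inside the ratio to keep zero-probability entries
#' finite.
#'
#' @param pwm 4 x W probability matrix.
#' @param background background probability per base (default 0.25).
#' @param pseudocount added to numerator and denominator inside the log
#'   (default 1e-3).
#' @return 4 x W numeric matrix of log2 odds.
#' @export
pwmLogOdds <- function(pwm, background = 0.25, pseudocount = 1e-3) {
  pwm <- .validPWM(pwm)
  log2((pwm + pseudocount) / (background + pseudocount))
}

# best log-odds hit of pwm in the character sequence s, scanning both
# strands; returns list(pos, strand, score) with ties broken leftmost,
# then '+'
.scanPWMBest <- function(s, lo) {
  W <- ncol(lo)
  L <- nchar(s)
  if (L < W) return(NULL)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES)
  nStart <- L - W + 1L
  fwd <- numeric(nStart); rev_ <- numeric(nStart)
  # reverse-strand score of fragment [i, i+W-1]: complement base at
  # reversed column
  loRC <- lo[4:1, W:1, drop = FALSE]
  for (j in seq_len(W)) {
    b <- idx[j:(j + nStart - 1L)]
    colF <- lo[, j]; colR <- loRC[, j]
    v <- colF[b]; v[is.na(v)] <- -Inf      # N never part of a best hit
    fwd <- fwd + v
    v2 <- colR[b]; v2[is.na(v2)] <- -Inf
    rev_ <- rev_ + v2
  }
  allBest <- max(fwd, rev_)
  if (!is.finite(allBest)) return(NULL)
  # leftmost, then '+'
  fi <- which(fwd == allBest)
  ri <- which(rev_ == allBest)
  posF <- if (length(fi)) fi[1L] else Inf
  posR <- if (length(ri)) ri[1L] else Inf
  if (posF <= posR) list(pos = posF, strand = "+", score = allBest)
  else list(pos = posR, strand = "-", score = allBest)
}
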