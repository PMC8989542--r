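# Time-dependent (position-inhomogeneous) Markov-chain machinery used by
# the simulation studies: fit order-1..3 chains on aligned fixed-length
# sequence sets, simulate from them, random-composition baselines,
# top-decile selection, and PWM motif simulation with random padding.

# integer base matrix (n x L, values 1..4) from an equal-width set
.baseMatrix <- function(seqs) {
  chars <- .asDNAChar(validateDNA(seqs))
  L <- unique(nchar(chars))
  if (length(L) != 1L) stop("sequences must all have the same length")
  m <- matrix(match(unlist(strsplit(chars, "", fixed = TRUE)), .BASES),
              nrow = length(chars), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("N bases are not allowed in Markov-chain fitting")
  m
}

# context index (1-based, lexicographic, oldest base first) from the m
# previous base columns
.ctxIndex <- function(bm, t, m) {
  if (m == 0L) return(rep.int(1L, nrow(bm)))
  idx <- rep.int(0L, nrow(bm))
  for (j in seq_len(m)) idx <- idx * 4L + (bm[, t - m + j - 1L] - 1L)
  idx + 1L
}

#' Fit a time-dependent Markov chain on an aligned sequence set
#'
#' Estimates, for every position t of the alignment, the conditional
#' distribution of the base at t given the previous `min(t-1, order)`
#' bases, with additive pseudocount smoothing.  With pseudocount 0 the
#' fitted chain captures the position-specific (k+1)-mer distribution of
#' the training set exactly in expectation; contexts never observed fall
#' back to the uniform distribution.
#'
#' @param seqs equal-length, N-free sequences (`DNAStringSet` or
#'   character).
#' @param order Markov order, 1-3.
#' @param pseudocount additive smoothing constant (default 0).
#' @return a [TimeDependentMarkov-class].
#' @export
fitTDMC <- function(seqs, order, pseudocount = 0) {
  order <- as.integer(order)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  bm <- .baseMatrix(seqs)
  L <- ncol(bm)
  tables <- vector("list", L)
  for (t in seq_len(L)) {
    m <- min(t - 1L, order)
    nctx <- 4L^m
    ctx <- .ctxIndex(bm, t, m)
    counts <- matrix(0, nctx, 4L)
    tb <- table(factor(ctx, levels = seq_len(nctx)),
                factor(bm[, t], levels = 1:4))
    counts[] <- as.numeric(tb)
    counts <- counts + pseudocount
    rs <- rowSums(counts)
    p <- counts / ifelse(rs == 0, 1, rs)
    p[rs == 0, ] <- 0.25               # unseen context: uniform fallback
    colnames(p) <- .BASES
    tables[[t]] <- p
  }
  new("TimeDependentMarkov", order = order, length = L, tables = tables,
      pseudocount = pseudocount)
}

# vectorised categorical draw: p is n x 4 with rows summing to 1
.sampleBase <- function(p) {
  u <- stats::runif(nrow(p))
  cp1 <- p[, 1L]; cp2 <- cp1 + p[, 2L]; cp3 <- cp2 + p[, 3L]
  1L + (u > cp1) + (u > cp2) + (u > cp3)
}

.collapseRows <- function(bm) {
  ch <- matrix(.BASES[bm], nrow(bm), ncol(bm))
  apply(ch, 1L, paste, collapse = "")
}

#' Simulate sequences from a time-dependent Markov chain
#'
#' Samples each sequence left to right from the position-specific
#' conditional distributions.
#'
#' @param model a [TimeDependentMarkov-class].
#' @param n number of sequences.
#' @param seed integer seed; the same seed reproduces the same output.
#' @return a `DNAStringSet` of `n` sequences of the model length.
#' @export
simulateTDMC <- function(model, n, seed = 1L) {
  stopifnot(is(model, "TimeDependentMarkov"))
  set.seed(seed)
  L <- model@length
  bm <- matrix(0L, n, L)
  for (t in seq_len(L)) {
    m <- min(t - 1L, model@order)
    ctx <- .ctxIndex(bm, t, m)
    bm[, t] <- .sampleBase(model@tables[[t]][ctx, , drop = FALSE])
  }
  Biostrings::DNAStringSet(.collapseRows(bm))
}

#' Marginal base composition of a sequence set
#'
#' @param seqs `DNAStringSet` or character vector.
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
fitMarginal <- function(seqs) {
  x <- validateDNA(seqs)
  af <- colSums(Biostrings::alphabetFrequency(x)[, .BASES, drop = FALSE])
  af / sum(af)
}

#' Simulate i.i.d. random sequences from a base composition
#'
#' @param composition probabilities for (A, C, G, T), summing to 1.
#' @param L sequence length in bp.
#' @param n number of sequences.
#' @param seed integer seed.
#' @return a `DNAStringSet`.
#' @export
simulateRandom <- function(composition, L, n, seed = 1L) {
  composition <- as.numeric(composition)
  if (length(composition) != 4L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-6)
    stop("composition must be 4 non-negative probabilities summing to 1")
  set.seed(seed)
  bm <- matrix(sample.int(4L, n * L, replace = TRUE, prob = composition),
               n, L)
  Biostrings::DNAStringSet(.collapseRows(bm))
}

#' Select items scoring above the 90th percentile
#'
#' The threshold is the empirical 90th percentile under the
#' linear-interpolation quantile definition (R type 7); selection is
#' strictly above the threshold, so fully tied inputs select nothing.
#'
#' @param seqs any subsettable collection (e.g. `DNAStringSet`).
#' @param scores numeric, one score per item.
#' @return the selected subset, with attributes `idx` (indices kept) and
#'   `threshold` (the percentile used).
#' @export
selectTopDecile <- function(seqs, scores) {
  if (length(seqs) == 0L) stop("empty input")
  if (length(seqs) != length(scores)) stop("length mismatch")
  thr <- stats::quantile(scores, 0.9, type = 7, names = FALSE)
  keep <- which(scores > thr)
  out <- seqs[keep]
  attr(out, "idx") <- keep
  attr(out, "threshold") <- thr
  out
}

#' Simulate PWM motif sequences padded to a fixed total length
#'
#' Draws a motif column-wise from the PWM, then adds equal-length random
#' pads on both sides until the total length is reached (e.g. a 19-bp
#' motif padded to 201 bp carries 91 random bp on each side, the motif
#' occupying positions 92..110).
#'
#' @param pwm a 4 x W probability matrix (rows A, C, G, T), e.g. from
#'   [readJASPAR()].
#' @param totalLength total sequence length; `totalLength - ncol(pwm)`
#'   must be even.
#' @param n number of sequences.
#' @param seed integer seed.
#' @param padComp base composition of the random pads (default uniform).
#' @return a `DNAStringSet` with attributes `motifStart` and `motifEnd`
#'   (1-based inclusive motif coordinates).
#' @export
simulatePWMPadded <- function(pwm, totalLength = 201L, n, seed = 1L,
                              padComp = rep(0.25, 4)) {
  pwm <- .validPWM(pwm)
  W <- ncol(pwm)
  pad <- totalLength - W
  if (pad < 0) stop("totalLength shorter than the motif")
  if (pad %% 2L != 0L)
    stop(sprintf(paste0("totalLength - motif width must be even; nearest",
                        " valid totals are %d and %d"),
                 totalLength - 1L, totalLength + 1L))
  pad <- pad %/% 2L
  padComp <- as.numeric(padComp)
  if (length(padComp) != 4L || abs(sum(padComp) - 1) > 1e-6)
    stop("padComp must be 4 probabilities summing to 1")
  set.seed(seed)
  bm <- matrix(0L, n, totalLength)
  if (pad > 0) {
    bm[, seq_len(pad)] <-
      sample.int(4L, n * pad, replace = TRUE, prob = padComp)
    bm[, pad + W + seq_len(pad)] <-
      sample.int(4L, n * pad, replace = TRUE, prob = padComp)
  }
  for (j in seq_len(W))
    bm[, pad + j] <- .sampleBase(matrix(pwm[, j], n, 4L, byrow = TRUE))
  out <- Biostrings::DNAStringSet(.collapseRows(bm))
  attr(out, "motifStart") <- pad + 1L
  attr(out, "motifEnd") <- pad + W
  out
}

#' Serialize / restore a fitted Markov chain as JSON
#'
#' @param model a [TimeDependentMarkov-class].
#' @param path output (input) path.
#' @return `writeTDMC` returns `path` invisibly; `readTDMC` the model.
#' @export
writeTDMC <- function(model, path) {
  obj <- list(order = model@order, length = model@length,
              pseudocount = model@pseudocount,
              tables = lapply(model@tables, function(m)
                unname(split(m, row(m)))))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeTDMC
#' @export
readTDMC <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  tables <- lapply(obj$tables, function(tt) {
    m <- if (is.matrix(tt)) tt
         else if (is.list(tt)) do.call(rbind, lapply(tt, as.numeric))
         else matrix(tt, nrow = 1L)
    colnames(m) <- .BASES
    m
  })
  new("TimeDependentMarkov", order = as.integer(obj$order),
      length = as.integer(obj$length), tables = tables,
      pseudocount = obj$pseudocount)
}

#' Position-specific empirical k-mer distribution of a sequence set
#'
#' @param seqs equal-length N-free sequences.
#' @param k k-mer size.
#' @return matrix with one row per k-mer end position (k..L) and 4^k
#'   columns (k-mers in lexicographic A<C<G<T order, oldest base first),
#'   rows summing to 1.
#' @export
empiricalKmerDist <- function(seqs, k) {
  bm <- .baseMatrix(seqs)
  L <- ncol(bm)
  k <- as.integer(k)
  if (k < 1L || k > L) stop("invalid k")
  out <- matrix(0, L - k + 1L, 4L^k)
  for (t in k:L) {
    idx <- rep.int(0L, nrow(bm))
    for (j in seq_len(k)) idx <- idx * 4L + (bm[, t - k + j] - 1L)
    out[t - k + 1L, ] <- tabulate(idx + 1L, nbins = 4L^k) / nrow(bm)
  }
  out
}

#' Expected position-specific k-mer distribution of a fitted chain
#'
#' Computed analytically by forward propagation of the joint distribution
#' over the trailing bases, with no simulation noise.  For a chain of
#' order >= k-1 fitted with pseudocount 0, this reproduces the training
#' set's position-specific k-mer distribution exactly (the k-mer capture
#' property).
#'
#' @param model a [TimeDependentMarkov-class].
#' @param k k-mer size.
#' @return matrix as in [empiricalKmerDist()].
#' @export
tdmcKmerDist <- function(model, k) {
  stopifnot(is(model, "TimeDependentMarkov"))
  k <- as.integer(k)
  L <- model@length
  if (k < 1L || k > L) stop("invalid k")
  w <- max(k, model@order)
  # joint over the last min(t, w) bases, oldest-first base-4 indexing
  joint <- as.numeric(model@tables[[1L]][1L, ])
  out <- matrix(0, L - k + 1L, 4L^k)
  if (k == 1L) out[1L, ] <- joint
  for (t in 2:L) {
    j <- min(t - 1L, w)
    m <- min(t - 1L, model@order)
    nOld <- 4L^j
    states <- 0:(nOld - 1L)
    ctx <- states %% 4L^m
    grow <- j < w
    nNew <- if (grow) nOld * 4L else nOld
    newJoint <- numeric(nNew)
    tab <- model@tables[[t]]
    for (b in 0:3) {
      pb <- joint * tab[ctx + 1L, b + 1L]
      tgt <- if (grow) states * 4L + b
             else (states %% 4L^(w - 1L)) * 4L + b
      add <- vapply(split(pb, tgt), sum, numeric(1))
      ai <- as.integer(names(add)) + 1L
      newJoint[ai] <- newJoint[ai] + add
    }
    joint <- newJoint
    if (t >= k) {
      jj <- min(t, w)
      tgt <- (0:(4L^jj - 1L)) %% 4L^k
      marg <- numeric(4L^k)
      add <- vapply(split(joint, tgt), sum, numeric(1))
      ai <- as.integer(names(add)) + 1L
      marg[ai] <- add
      out[t - k + 1L, ] <- marg
    }
  }
  out
}
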