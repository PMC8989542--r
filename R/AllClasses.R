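#' SequenceLibrary: fixed-length sequences with cyclizability labels
#'
#' The training/evaluation unit: a set of DNA sequences paired with
#' real-valued intrinsic cyclizability scores.  Measured loop-seq scores
#' are comparable across libraries only up to an additive library-specific
#' constant, which is why evaluation uses Pearson correlation.
#'
#' @slot seqs a [Biostrings::DNAStringSet] (alphabet A/C/G/T/N).
#' @slot labels numeric vector, one score per sequence.
#' @slot name character scalar library name.
#' @slot meta list of free-form metadata (generation parameters, class
#'   assignments, standardization constants).
#'
#' @aliases SequenceLibrary-class
#' @exportClass SequenceLibrary
setClass("SequenceLibrary",
  slots = c(seqs = "DNAStringSet", labels = "numeric",
            name = "character", meta = "list"))

setValidity("SequenceLibrary", function(object) {
  if (length(object@seqs) != length(object@labels))
    return("number of sequences and labels differ")
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (anyNA(object@labels)) return("labels contain NA")
  TRUE
})

#' Construct a SequenceLibrary
#'
#' @param seqs character vector or [Biostrings::DNAStringSet].
#' @param labels numeric scores, one per sequence.
#' @param name library name.
#' @param meta optional metadata list.
#' @return a [SequenceLibrary-class] object.
#' @examples
#' lib <- sequenceLibrary(c("ACGTA", "TTTTT"), c(0.1, -0.2))
#' length(lib)
#' @export
sequenceLibrary <- function(seqs, labels, name = "library", meta = list()) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  validateDNA(seqs)
  new("SequenceLibrary", seqs = seqs, labels = as.numeric(labels),
      name = name, meta = meta)
}

#' IRLSTMModel: the deployable cyclizability predictor
#'
#' Bundles the architecture configuration, the learned parameters, the
#' batch-normalization running statistics, the linear detrend coefficients
#' and the label-standardization constants.  Predictions are made by
#' [predictCScore()] / [predictTrack()].
#'
#' @slot config architecture configuration from [irlstmConfig()].
#' @slot params named list of weight arrays.
#' @slot bnStats named list of batch-normalization running means/variances.
#' @slot detrend numeric `c(a, b)`: the correction `a + b * raw` applied to
#'   the reverse-complement-averaged raw network output.
#' @slot labelMean,labelSd standardization constants of the training labels.
#' @slot seed integer seed used for weight initialization.
#' @slot history data.frame of per-epoch training/validation loss.
#'
#' @aliases IRLSTMModel-class
#' @exportClass IRLSTMModel
setClass("IRLSTMModel",
  slots = c(config = "list", params = "list", bnStats = "list",
            detrend = "numeric", labelMean = "numeric", labelSd = "numeric",
            seed = "integer", history = "data.frame"))

setValidity("IRLSTMModel", function(object) {
  if (length(object@detrend) != 2L || !all(is.finite(object@detrend)))
    return("'detrend' must be two finite numbers c(a, b)")
  if (object@detrend[2L] == 0) return("detrend slope must be non-zero")
  if (length(object@labelSd) != 1L || object@labelSd <= 0)
    return("'labelSd' must be a single positive number")
  TRUE
})

#' CScoreTrack: per-base-pair predicted C-scores on one sequence
#'
#' Scores are anchored at window centers: the score at 1-based position p
#' is the prediction for the 50-bp fragment `[p - 24, p + 25]`, so a
#' window starting at position 1 is reported at position 25.  Windows
#' overlapping an N base are skipped and produce gaps.
#'
#' @slot chrom character scalar sequence/chromosome name.
#' @slot pos integer vector of 1-based center positions, strictly increasing.
#' @slot score numeric C-scores, one per position.
#' @slot windowWidth integer window width (50).
#'
#' @aliases CScoreTrack-class
#' @exportClass CScoreTrack
setClass("CScoreTrack",
  slots = c(chrom = "character", pos = "integer", score = "numeric",
            windowWidth = "integer"))

setValidity("CScoreTrack", function(object) {
  if (length(object@pos) != length(object@score))
    return("positions and scores differ in length")
  if (length(object@pos) && is.unsorted(object@pos, strictly = TRUE))
    return("positions must be strictly increasing")
  half <- (object@windowWidth %/% 2L)
  if (length(object@pos) && min(object@pos) < half)
    return("position precedes the first full window center")
  TRUE
})

#' Construct a CScoreTrack
#' @param chrom sequence name.
#' @param pos integer 1-based center positions (strictly increasing).
#' @param score numeric scores.
#' @param windowWidth window width in bp (default 50).
#' @return a [CScoreTrack-class] object.
#' @export
cScoreTrack <- function(chrom, pos, score, windowWidth = 50L) {
  new("CScoreTrack", chrom = as.character(chrom), pos = as.integer(pos),
      score = as.numeric(score), windowWidth = as.integer(windowWidth))
}

#' TimeDependentMarkov: position-inhomogeneous Markov chain over DNA bases
#'
#' An order-k chain fitted on an alignment of equal-length sequences: at
#' every position t the conditional distribution over A/C/G/T given the
#' previous `min(t - 1, k)` bases.  Captures the position-specific
#' (k+1)-mer distribution of the training alignment.
#'
#' @slot order integer Markov order (1-3).
#' @slot length integer alignment length L in bp.
#' @slot tables list of L matrices; entry t has `4^min(t-1, k)` rows
#'   (contexts in lexicographic A<C<G<T order, oldest base first) and 4
#'   columns (A, C, G, T), each row summing to 1.
#' @slot pseudocount numeric additive smoothing constant.
#'
#' @aliases TimeDependentMarkov-class
#' @exportClass TimeDependentMarkov
setClass("TimeDependentMarkov",
  slots = c(order = "integer", length = "integer", tables = "list",
            pseudocount = "numeric"))

setValidity("TimeDependentMarkov", function(object) {
  if (!object@order %in% 1:3) return("order must be 1, 2 or 3")
  if (length(object@tables) != object@length)
    return("one conditional table per position required")
  for (t in seq_along(object@tables)) {
    tab <- object@tables[[t]]
    m <- min(t - 1L, object@order)
    if (!is.matrix(tab) || nrow(tab) != 4L^m || ncol(tab) != 4L)
      return(sprintf("table %d has wrong dimensions", t))
    if (any(abs(rowSums(tab) - 1) > 1e-9))
      return(sprintf("table %d rows do not sum to 1", t))
  }
  TRUE
})

#' CVResult: outcome of k-fold cross-validation
#'
#' @slot folds integer fold assignment per sequence (1..k).
#' @slot pearson numeric held-out Pearson correlation per fold.
#' @slot bestFold integer index of the best-performing fold (ties broken by
#'   lowest index).
#' @slot models list of per-fold [IRLSTMModel-class] objects.
#' @slot report data.frame (fold, n_train, n_test, pearson, epochs_run).
#'
#' @aliases CVResult-class
#' @exportClass CVResult
setClass("CVResult",
  slots = c(folds = "integer", pearson = "numeric", bestFold = "integer",
            models = "list", report = "data.frame"))
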