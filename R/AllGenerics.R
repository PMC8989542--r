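#' @rdname predictCScore
#' @export
setGeneric("predictCScore", function(model, seqs, ...)
  standardGeneric("predictCScore"))

#' @rdname predictTrack
#' @export
setGeneric("predictTrack", function(model, seq, ...)
  standardGeneric("predictTrack"))

#' @rdname fitDetrend
#' @export
setGeneric("fitDetrend", function(model, calib, ...)
  standardGeneric("fitDetrend"))

#' Accessors for SequenceLibrary and CScoreTrack
#'
#' `sequences()` returns the DNAStringSet, `cycLabels()` the label vector,
#' `trackPositions()`/`trackScores()` the center positions and scores of a
#' track.
#'
#' @param x a [SequenceLibrary-class] or [CScoreTrack-class] object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("cycLabels", function(x) standardGeneric("cycLabels"))

#' @rdname accessors
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' @rdname accessors
#' @export
setGeneric("trackScores", function(x) standardGeneric("trackScores"))

#' @rdname accessors
#' @export
setMethod("sequences", "SequenceLibrary", function(x) x@seqs)

#' @rdname accessors
#' @export
setMethod("cycLabels", "SequenceLibrary", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("trackPositions", "CScoreTrack", function(x) x@pos)

#' @rdname accessors
#' @export
setMethod("trackScores", "CScoreTrack", function(x) x@score)

#' @describeIn accessors number of sequences in the library
#' @export
setMethod("length", "SequenceLibrary", function(x) length(x@seqs))

#' @describeIn accessors number of scored positions in the track
#' @export
setMethod("length", "CScoreTrack", function(x) length(x@pos))

#' @describeIn accessors subset a library
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "SequenceLibrary", function(x, i, j, ..., drop = TRUE) {
  new("SequenceLibrary", seqs = x@seqs[i], labels = x@labels[i],
      name = x@name, meta = x@meta)
})

setMethod("show", "SequenceLibrary", function(object) {
  w <- unique(width(object@seqs))
  cat(sprintf("SequenceLibrary '%s': %d sequences (width%s %s)\n",
              object@name, length(object@seqs),
              if (length(w) > 1) "s" else "",
              paste(utils::head(w, 3), collapse = ",")))
  if (length(object@labels))
    cat(sprintf("  labels: mean %.3f, sd %.3f\n", mean(object@labels),
                stats::sd(object@labels)))
})

setMethod("show", "IRLSTMModel", function(object) {
  cat("IRLSTMModel (inception-residual + LSTM cyclizability predictor)\n")
  cat(sprintf("  input length : %d bp\n", object@config$inputLength))
  cat(sprintf("  parameters   : %d trainable\n", nParams(object)))
  cat(sprintf("  detrend      : a = %.4f, b = %.4f\n",
              object@detrend[1], object@detrend[2]))
  cat(sprintf("  label scale  : mean %.4f, sd %.4f\n",
              object@labelMean, object@labelSd))
  if (nrow(object@history))
    cat(sprintf("  trained      : %d epochs, best val MSE %.4f\n",
                nrow(object@history), min(object@history$val_mse)))
})

setMethod("show", "CScoreTrack", function(object) {
  cat(sprintf("CScoreTrack on %s: %d scores", object@chrom,
              length(object@pos)))
  if (length(object@pos))
    cat(sprintf(" at centers %d..%d", min(object@pos), max(object@pos)))
  cat(sprintf(" (window %d bp)\n", object@windowWidth))
})

setMethod("show", "TimeDependentMarkov", function(object) {
  cat(sprintf(
    "TimeDependentMarkov: order %d, length %d bp, pseudocount %g\n",
    object@order, object@length, object@pseudocount))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d folds, Pearson %.3f-%.3f (best fold %d)\n",
              length(object@pearson), min(object@pearson),
              max(object@pearson), object@bestFold))
})
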