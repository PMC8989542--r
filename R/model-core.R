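#' Build an (untrained) IR+LSTM cyclizability model
#'
#' Constructs the network with freshly initialised weights
#' (variance-scaling uniform, seeded), identity detrend `(a, b) = (0, 1)`
#' and identity label scale.  Shape consistency between the concatenated
#' inception branches and the residual shortcut is checked at build time.
#'
#' @param config configuration from [irlstmConfig()].
#' @param seed integer seed for weight initialization (recorded in the
#'   model).
#' @return an [IRLSTMModel-class] with untrained weights.
#' @examples
#' m <- buildIRLSTM(seed = 1)
#' nParams(m)
#' @export
buildIRLSTM <- function(config = irlstmConfig(), seed = 1L) {
  set.seed(seed)
  ini <- nnInit(config)
  new("IRLSTMModel", config = config, params = ini$params,
      bnStats = ini$bnStats, detrend = c(a = 0, b = 1),
      labelMean = 0, labelSd = 1, seed = as.integer(seed),
      history = data.frame())
}

#' Number of trainable parameters
#' @param model an [IRLSTMModel-class].
#' @return integer count of trainable parameters (convolution, batch-norm
#'   gamma/beta, LSTM and dense weights and biases).
#' @export
nParams <- function(model) nnCountParams(model@params)

#' Raw network output for a batch of encoded sequences
#'
#' Evaluation-mode forward pass (dropout inactive, batch normalization
#' using stored running statistics); deterministic.
#'
#' @param model an [IRLSTMModel-class].
#' @param X either a single one-hot matrix (L x 4) or an L x 4 x B array.
#' @param chunk internal batch size; must not change results.
#' @return numeric vector of raw (un-detrended, single-orientation)
#'   outputs.
#' @export
predictRaw <- function(model, X, chunk = 1024L) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  if (dim(X)[1L] != model@config$inputLength)
    stop(sprintf("input has %d rows; model expects %d", dim(X)[1L],
                 model@config$inputLength))
  if (dim(X)[2L] != 4L) stop("input must have 4 channels (A,C,G,T)")
  nnPredict(model@params, model@bnStats, model@config, X, chunk = chunk)
}

# encode sequences (character vector, all width L) into an L x 4 x B array
.encodeBatch <- function(chars, L) {
  X <- array(0, c(L, 4L, length(chars)))
  for (i in seq_along(chars)) X[, , i] <- oneHotEncode(chars[i])
  X
}

# reverse-complement-averaged raw output for width-50 sequences
.rawAveraged <- function(model, chars, chunk = 1024L) {
  L <- model@config$inputLength
  X <- .encodeBatch(chars, L)
  Xrc <- X[rev(seq_len(L)), c(4L, 3L, 2L, 1L), , drop = FALSE]
  both <- array(0, c(L, 4L, 2L * length(chars)))
  n <- length(chars)
  both[, , seq_len(n)] <- X
  both[, , n + seq_len(n)] <- Xrc
  out <- nnPredict(model@params, model@bnStats, model@config, both,
                   chunk = chunk)
  (out[seq_len(n)] + out[n + seq_len(n)]) / 2
}

#' Predict the C-score of 50-bp sequences
#'
#' Each sequence and its reverse complement are scored independently by
#' the network; the two raw outputs are averaged and linearly detrended:
#' `C = a + b * mean(raw(s), raw(rc(s)))`.  By construction the C-score
#' of a sequence equals that of its reverse complement.
#'
#' The C-score is on the standardized scale of the training library
#' (mean 0, sd 1), so a value of 1.96 sits 1.96 standard deviations above
#' the training-genome average, the ~97.5% normal quantile.
#'
#' @param model a trained [IRLSTMModel-class].
#' @param seqs `DNAStringSet`, `DNAString` or character vector; every
#'   sequence must have exactly the model input length (50 bp).  For
#'   longer sequences use [predictTrack()].
#' @param ... unused.
#' @return numeric vector of C-scores, one per sequence.
#' @rdname predictCScore
#' @export
setMethod("predictCScore", "IRLSTMModel", function(model, seqs, ...) {
  chars <- .asDNAChar(validateDNA(seqs))
  L <- model@config$inputLength
  if (any(nchar(chars) != L))
    stop(sprintf(paste0("all sequences must be exactly %d bp; for longer",
                        " sequences use predictTrack() for sliding-window",
                        " prediction"), L))
  raw <- .rawAveraged(model, chars)
  unname(model@detrend[1L] + model@detrend[2L] * raw)
})

#' Save / load a trained model
#'
#' The archive holds the architecture configuration, all learned weights,
#' the batch-normalization running statistics, detrend coefficients,
#' label-standardization constants, the channel order and the
#' initialization seed.  A save/load round trip reproduces predictions
#' bit-identically.
#'
#' @param model an [IRLSTMModel-class].
#' @param path file path for the model archive (.rds).
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "IRLSTMModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "IRLSTMModel"))
    stop("file does not contain an IRLSTMModel: ", path)
  validObject(model)
  model
}

#' Export the model configuration as JSON
#'
#' Writes the architecture configuration, detrend coefficients, label
#' statistics, channel order and seed (everything except the weight
#' arrays) as human-readable JSON.
#'
#' @param model an [IRLSTMModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModelConfigJSON <- function(model, path) {
  meta <- list(config = model@config,
               detrend = as.list(stats::setNames(model@detrend, c("a", "b"))),
               labelMean = model@labelMean, labelSd = model@labelSd,
               channelOrder = model@config$channelOrder,
               seed = model@seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}
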