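#' Standardize library labels to zero mean and unit variance
#'
#' Training labels are standardized so the predicted C-score reads as a
#' z-score relative to the training-genome average (e.g. 1.96 is the
#' ~97.5% normal quantile).  The constants are returned for later
#' un-scaling and are stored in trained models.
#'
#' @param lib a [SequenceLibrary-class].
#' @return list with elements `lib` (standardized library), `mean` and
#'   `sd` (sample mean and sample standard deviation of the input labels).
#' @export
standardizeLabels <- function(lib) {
  stopifnot(is(lib, "SequenceLibrary"))
  m <- mean(lib@labels)
  s <- stats::sd(lib@labels)
  if (!is.finite(s) || s == 0)
    stop("degenerate labels: zero variance, cannot standardize")
  out <- lib
  out@labels <- (lib@labels - m) / s
  out@meta$labelMean <- m
  out@meta$labelSd <- s
  list(lib = out, mean = m, sd = s)
}

#' Random k-fold partition
#'
#' @param n number of items.
#' @param k number of folds (default 10).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return integer vector of fold assignments in `1..k`; fold sizes differ
#'   by at most 1.
#' @export
kfoldSplit <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop(sprintf("cannot split %d items into %d folds", n, k))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Training hyperparameters
#'
#' Stochastic gradient descent with the rmsprop optimiser and MSE loss;
#' early stopping monitors validation MSE with checkpointing of the best
#' weights.
#'
#' @param batchSize minibatch size.
#' @param maxEpochs maximum number of epochs.
#' @param patience early-stopping patience: training stops once validation
#'   MSE has failed to improve for more than `patience` consecutive
#'   epochs; the returned weights are the best checkpoint, not the final
#'   epoch.
#' @param lr,rho,eps rmsprop learning rate, decay and stabiliser.
#' @param valFraction fraction of the training folds carved out as the
#'   internal validation split during cross-validation.
#' @return list of hyperparameters.
#' @export
trainHyper <- function(batchSize = 128L, maxEpochs = 100L, patience = 5L,
                       lr = 1e-3, rho = 0.9, eps = 1e-7,
                       valFraction = 0.1) {
  list(batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
       patience = as.integer(patience), lr = lr, rho = rho, eps = eps,
       valFraction = valFraction)
}

# validation MSE of raw single-orientation outputs
.valMSE <- function(params, bnStats, cfg, Xval, yval) {
  pred <- nnPredict(params, bnStats, cfg, Xval)
  mean((pred - yval)^2)
}

#' Train an IR+LSTM model
#'
#' Minimises MSE by rmsprop on minibatches, with early stopping: after
#' every epoch the validation MSE is computed in evaluation mode, and the
#' weights with the lowest validation MSE seen so far are checkpointed and
#' returned.  After training, the linear detrend is calibrated on the
#' validation set (see [fitDetrend()]), correcting the mean drift and
#' variance shrinkage of raw network outputs.
#'
#' @param train,val disjoint [SequenceLibrary-class] objects with
#'   standardized labels; all sequences at the model input length.
#' @param config architecture configuration, [irlstmConfig()].
#' @param hyper hyperparameters, [trainHyper()].
#' @param seed integer seed controlling weight initialization, batch
#'   shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return a trained [IRLSTMModel-class] with the training history
#'   attached.
#' @export
trainModel <- function(train, val, config = irlstmConfig(),
                       hyper = trainHyper(), seed = 1L, verbose = FALSE) {
  stopifnot(is(train, "SequenceLibrary"), is(val, "SequenceLibrary"))
  if (length(val) == 0L) stop("empty validation set")
  if (length(train) == 0L) stop("empty training set")
  L <- config$inputLength
  trc <- .asDNAChar(train@seqs)
  vac <- .asDNAChar(val@seqs)
  if (any(nchar(c(trc, vac)) != L))
    stop(sprintf("all training sequences must be %d bp", L))
  set.seed(seed)
  ini <- nnInit(config)
  params <- ini$params; bnStats <- ini$bnStats
  state <- rmspropInit(params)
  Xtr <- .encodeBatch(trc, L); ytr <- train@labels
  Xva <- .encodeBatch(vac, L); yva <- val@labels
  n <- length(ytr)
  best <- list(mse = Inf, params = params, bnStats = bnStats, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_mse = numeric(),
                     val_mse = numeric())
  for (epoch in seq_len(hyper$maxEpochs)) {
    idx <- sample.int(n)
    nb <- ceiling(n / hyper$batchSize)
    eloss <- 0
    for (b in seq_len(nb)) {
      take <- idx[((b - 1L) * hyper$batchSize + 1L):
                    min(n, b * hyper$batchSize)]
      Xb <- Xtr[, , take, drop = FALSE]
      yb <- ytr[take]
      masks <- nnDropoutMasks(config, length(take))
      fw <- nnForward(params, bnStats, config, Xb, training = TRUE,
                      masks = masks)
      err <- fw$out - yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop(sprintf("divergence: non-finite loss at epoch %d", epoch))
      eloss <- eloss + loss * length(take)
      bw <- nnBackward(params, config, fw$cache, 2 * err / length(take))
      up <- rmspropStep(params, bw$grads, state, lr = hyper$lr,
                        rho = hyper$rho, eps = hyper$eps)
      params <- up$params; state <- up$state
      bnStats <- nnUpdateBN(bnStats, fw$stats, config$bnMomentum)
    }
    vmse <- .valMSE(params, bnStats, config, Xva, yva)
    hist <- rbind(hist, data.frame(epoch = epoch, train_mse = eloss / n,
                                   val_mse = vmse))
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", epoch, eloss / n,
                      vmse))
    if (vmse < best$mse) {
      best <- list(mse = vmse, params = params, bnStats = bnStats,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > hyper$patience) break
    }
  }
  model <- new("IRLSTMModel", config = config, params = best$params,
               bnStats = best$bnStats, detrend = c(a = 0, b = 1),
               labelMean = if (!is.null(train@meta$labelMean))
                 train@meta$labelMean else 0,
               labelSd = if (!is.null(train@meta$labelSd))
                 train@meta$labelSd else 1,
               seed = as.integer(seed), history = hist)
  model@detrend <- fitDetrend(model, val)
  model
}

#' Calibrate the linear detrend of a model
#'
#' Raw network outputs show a mean drift and variance shrinkage relative
#' to the labels.  The detrend is the least-squares regression of the
#' calibration labels on the reverse-complement-averaged raw outputs,
#' `label ~ a + b * raw`; predictions then apply `a + b * raw`.  On the
#' calibration set this makes the corrected mean equal the label mean and
#' the OLS slope of labels on corrected predictions equal 1 (least-squares
#' identities).  Calibration should use held-out data (the internal
#' validation split), where raw outputs are not optimistically fitted.
#'
#' @param model an [IRLSTMModel-class], or a numeric vector of raw
#'   outputs.
#' @param calib a [SequenceLibrary-class] on the training label scale, or
#'   (for the numeric method) the numeric label vector.
#' @param ... unused.
#' @return numeric `c(a, b)`.
#' @rdname fitDetrend
#' @export
setMethod("fitDetrend", signature("IRLSTMModel", "SequenceLibrary"),
  function(model, calib, ...) {
    raw <- .rawAveraged(model, .asDNAChar(calib@seqs))
    fitDetrend(raw, calib@labels)
  })

#' @rdname fitDetrend
#' @export
setMethod("fitDetrend", signature("numeric", "numeric"),
  function(model, calib, ...) {
    raw <- model; labels <- calib
    if (length(raw) != length(labels)) stop("length mismatch")
    if (stats::var(raw) == 0)
      stop("zero variance in raw outputs; cannot detrend")
    fit <- stats::lm.fit(cbind(1, raw), labels)
    stats::setNames(as.numeric(fit$coefficients), c("a", "b"))
  })

#' Pearson correlation with the evaluation contract
#'
#' Prediction accuracy is evaluated by Pearson correlation, which is
#' invariant to the additive library-specific constant of measured
#' loop-seq scores.
#'
#' @param x,y numeric vectors of equal length (>= 2), both non-constant.
#' @return the product-moment correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y)
}

#' k-fold cross-validation of the IR+LSTM model
#'
#' For each fold, the model is trained on the remaining k-1 folds (with an
#' internal validation split carved out for early stopping and detrend
#' calibration) and evaluated by Pearson correlation on the held-out fold.
#' The best fold (highest held-out correlation, ties to the lowest index)
#' is flagged; its model is the deployable predictor.
#'
#' @param lib a standardized [SequenceLibrary-class].
#' @param config,hyper see [trainModel()].
#' @param k number of folds.
#' @param seed integer seed (fold assignment, per-fold training).
#' @param verbose print progress.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(lib, config = irlstmConfig(),
                          hyper = trainHyper(), k = 10L, seed = 1L,
                          verbose = FALSE) {
  stopifnot(is(lib, "SequenceLibrary"))
  folds <- kfoldSplit(length(lib), k = k, seed = seed)
  models <- vector("list", k)
  pearson <- numeric(k)
  rep <- data.frame(fold = integer(), n_train = integer(),
                    n_test = integer(), pearson = numeric(),
                    epochs_run = integer())
  for (f in seq_len(k)) {
    tr <- lib[folds != f]
    te <- lib[folds == f]
    set.seed(seed * 1000L + f)
    nin <- max(1L, round(hyper$valFraction * length(tr)))
    vidx <- sample.int(length(tr), nin)
    inval <- tr[vidx]
    intr <- tr[-vidx]
    m <- trainModel(intr, inval, config = config, hyper = hyper,
                    seed = seed * 100L + f, verbose = verbose)
    pred <- predictCScore(m, te@seqs)
    pearson[f] <- pearsonR(pred, te@labels)
    models[[f]] <- m
    rep <- rbind(rep, data.frame(fold = f, n_train = length(intr),
                                 n_test = length(te),
                                 pearson = pearson[f],
                                 epochs_run = nrow(m@history)))
    if (verbose)
      message(sprintf("fold %d/%d: r = %.3f", f, k, pearson[f]))
  }
  new("CVResult", folds = folds, pearson = pearson,
      bestFold = which.max(pearson)[1L], models = models, report = rep)
}

#' Write a cross-validation report as TSV
#' @param cv a [CVResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCVReport <- function(cv, path) {
  utils::write.table(cv@report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a training library as TSV
#'
#' Two columns: `sequence` and `score`.
#'
#' @param path file path.
#' @param name library name for the returned object.
#' @return `readLibraryTSV` returns a [SequenceLibrary-class];
#'   `writeLibraryTSV` returns `path` invisibly.
#' @export
readLibraryTSV <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "score") %in% names(df)))
    stop("training library must have columns 'sequence' and 'score'")
  sequenceLibrary(df$sequence, df$score, name = name)
}

#' @rdname readLibraryTSV
#' @param lib a [SequenceLibrary-class].
#' @export
writeLibraryTSV <- function(lib, path) {
  utils::write.table(
    data.frame(sequence = as.character(lib@seqs), score = lib@labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
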