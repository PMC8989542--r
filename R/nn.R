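# Composition of the inception-residual + LSTM network from the compiled
# layer primitives.  Activations are L x C x B arrays.  Every block caches
# what its backward pass needs; the training loop lives in training.R.
#
# Layer order (input one-hot 50 x 4):
#   stem   : conv 3x4 (base axis collapsed) -> ReLU -> BN -> dropout
#   branch1: conv 3x1 -> ReLU -> BN -> drop; conv 3x1 -> ReLU -> pool 2x1
#            -> BN -> drop
#   branch2: conv 11x1 -> ReLU -> BN -> drop; conv 21x1 -> ReLU -> pool 2x1
#            -> BN -> drop
#   concat branches (channels); residual add of the 2x1-max-pooled stem
#   output; pool 2x1 -> BN -> drop; LSTM (20 units, final state) -> drop;
#   dense -> scalar.

.BN_EPS_DEFAULT <- 1e-3

#' Architecture configuration for the IR+LSTM network
#'
#' Defaults follow the published architecture where stated (kernel sizes
#' 3x4, 3x1/3x1 and 11x1/21x1, stride 1, pool 2x1, dropout 0.2, 20 LSTM
#' units, length-preserving padding); filter counts are the smallest
#' symmetric choice that makes the residual addition shape-consistent:
#' the two 32-filter branches concatenate to the 64-channel stem output.
#'
#' @param inputLength input sequence length in bp (50).
#' @param stemFilters filters of the stem convolution (64).
#' @param branchFilters filters per inception branch (32); must satisfy
#'   `2 * branchFilters == stemFilters`.
#' @param branch1Kernels,branch2Kernels kernel widths of the two serial
#'   convolutions on each branch.
#' @param dropout dropout rate in `[0, 1)`.
#' @param lstmUnits LSTM hidden units.
#' @param bnEps,bnMomentum batch-normalization epsilon and running-average
#'   momentum.
#' @return a validated configuration list.
#' @export
irlstmConfig <- function(inputLength = 50L, stemFilters = 64L,
                         branchFilters = 32L, branch1Kernels = c(3L, 3L),
                         branch2Kernels = c(11L, 21L), dropout = 0.2,
                         lstmUnits = 20L, bnEps = .BN_EPS_DEFAULT,
                         bnMomentum = 0.9) {
  cfg <- list(inputLength = as.integer(inputLength),
              stemKernel = 3L,
              stemFilters = as.integer(stemFilters),
              branchFilters = as.integer(branchFilters),
              branch1Kernels = as.integer(branch1Kernels),
              branch2Kernels = as.integer(branch2Kernels),
              dropout = dropout, lstmUnits = as.integer(lstmUnits),
              bnEps = bnEps, bnMomentum = bnMomentum,
              channelOrder = .BASES)
  if (2L * cfg$branchFilters != cfg$stemFilters)
    stop("shape inconsistency: concatenated branches (2 x ",
         cfg$branchFilters, " channels) cannot be added to the ",
         cfg$stemFilters, "-channel shortcut; need 2*branchFilters == ",
         "stemFilters")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must be in [0, 1)")
  if (cfg$lstmUnits < 1L) stop("lstmUnits must be >= 1")
  if (cfg$inputLength < 8L) stop("inputLength too short for the pooling ",
                                 "cascade")
  cfg
}

# Glorot (variance-scaling) uniform draw using R's RNG
.glorot <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.nnConvNames <- c("stem", "b1c1", "b1c2", "b2c1", "b2c2")

# Initialise all parameters and BN running statistics.  Uses the current
# RNG state; callers seed it.
nnInit <- function(cfg) {
  Fs <- cfg$stemFilters; Fb <- cfg$branchFilters; H <- cfg$lstmUnits
  kdef <- list(stem = c(cfg$stemKernel, 4L, Fs),
               b1c1 = c(cfg$branch1Kernels[1], Fs, Fb),
               b1c2 = c(cfg$branch1Kernels[2], Fb, Fb),
               b2c1 = c(cfg$branch2Kernels[1], Fs, Fb),
               b2c2 = c(cfg$branch2Kernels[2], Fb, Fb))
  bnch <- c(stem = Fs, b1c1 = Fb, b1c2 = Fb, b2c1 = Fb, b2c2 = Fb,
            post = Fs)
  params <- list()
  for (nm in names(kdef)) {
    k <- kdef[[nm]]
    params[[paste0(nm, "_W")]] <-
      .glorot(k[1] * k[2], k[3], k[1] * k[2], k[1] * k[3])
    params[[paste0(nm, "_b")]] <- numeric(k[3])
  }
  for (nm in names(bnch)) {
    params[[paste0(nm, "_gamma")]] <- rep(1, bnch[[nm]])
    params[[paste0(nm, "_beta")]] <- numeric(bnch[[nm]])
  }
  params$lstm_Wx <- .glorot(Fs, 4L * H, Fs, H)
  params$lstm_Wh <- .glorot(H, 4L * H, H, H)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1          # forget-gate bias
  params$lstm_b <- b
  params$dense_W <- .glorot(H, 1L, H, 1L)
  params$dense_b <- 0
  bnStats <- list()
  for (nm in names(bnch)) {
    bnStats[[paste0(nm, "_mean")]] <- numeric(bnch[[nm]])
    bnStats[[paste0(nm, "_var")]] <- rep(1, bnch[[nm]])
  }
  list(params = params, bnStats = bnStats)
}

# Trainable-parameter count
nnCountParams <- function(params) {
  sum(vapply(params, length, integer(1)))
}

# Dropout masks for one training batch (inverted dropout scaling), drawn
# from R's RNG.  Shapes depend on the batch size B.
nnDropoutMasks <- function(cfg, B) {
  p <- cfg$dropout
  if (p == 0) return(NULL)
  L <- cfg$inputLength; Fs <- cfg$stemFilters; Fb <- cfg$branchFilters
  Lh <- L %/% 2L; Lq <- Lh %/% 2L
  mk <- function(d) array((stats::runif(prod(d)) >= p) / (1 - p), d)
  list(stem = mk(c(L, Fs, B)),
       b1c1 = mk(c(L, Fb, B)), b1c2 = mk(c(Lh, Fb, B)),
       b2c1 = mk(c(L, Fb, B)), b2c2 = mk(c(Lh, Fb, B)),
       post = mk(c(Lq, Fs, B)),
       lstm = matrix((stats::runif(B * cfg$lstmUnits) >= p) / (1 - p),
                     B, cfg$lstmUnits))
}

.convBlockFwd <- function(x, params, bnStats, cfg, name, pool, training,
                          mask) {
  cv <- conv1d_forward(x, params[[paste0(name, "_W")]],
                       params[[paste0(name, "_b")]])$y
  rmask <- cv > 0
  a <- cv * rmask
  pidx <- NULL; Lpre <- dim(a)[1L]
  if (pool) {
    pl <- maxpool2_forward(a)
    a <- pl$y; pidx <- pl$idx
  }
  bn <- bn_forward(a, params[[paste0(name, "_gamma")]],
                   params[[paste0(name, "_beta")]], training,
                   bnStats[[paste0(name, "_mean")]],
                   bnStats[[paste0(name, "_var")]], cfg$bnEps)
  out <- bn$y
  if (training && !is.null(mask)) out <- out * mask
  list(out = out,
       cache = list(x = x, rmask = rmask, pidx = pidx, Lpre = Lpre,
                    xhat = bn$xhat, var = bn$var, mask = mask),
       stats = list(mean = bn$mean, var = bn$var))
}

.convBlockBwd <- function(dout, params, cfg, name, cache) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  bnb <- bn_backward(cache$xhat, params[[paste0(name, "_gamma")]],
                     cache$var, dout, cfg$bnEps)
  da <- bnb$dx
  if (!is.null(cache$pidx)) da <- maxpool2_backward(cache$pidx, da,
                                                    cache$Lpre)
  da <- da * cache$rmask
  cb <- conv1d_backward(cache$x, params[[paste0(name, "_W")]], da)
  grads <- list(cb$dW, as.numeric(cb$db), as.numeric(bnb$dgamma),
                as.numeric(bnb$dbeta))
  names(grads) <- paste0(name, c("_W", "_b", "_gamma", "_beta"))
  list(dx = cb$dx, grads = grads)
}

# Full forward pass.  X: L x 4 x B array.  Returns the scalar outputs
# (length B), the cache for backward, and the per-layer BN batch stats.
nnForward <- function(params, bnStats, cfg, X, training = FALSE,
                      masks = NULL) {
  B <- dim(X)[3L]
  Fb <- cfg$branchFilters
  stem <- .convBlockFwd(X, params, bnStats, cfg, "stem", FALSE, training,
                        masks$stem)
  b1a <- .convBlockFwd(stem$out, params, bnStats, cfg, "b1c1", FALSE,
                       training, masks$b1c1)
  b1b <- .convBlockFwd(b1a$out, params, bnStats, cfg, "b1c2", TRUE,
                       training, masks$b1c2)
  b2a <- .convBlockFwd(stem$out, params, bnStats, cfg, "b2c1", FALSE,
                       training, masks$b2c1)
  b2b <- .convBlockFwd(b2a$out, params, bnStats, cfg, "b2c2", TRUE,
                       training, masks$b2c2)
  Lh <- dim(b1b$out)[1L]
  conc <- array(0, c(Lh, 2L * Fb, B))
  conc[, seq_len(Fb), ] <- b1b$out
  conc[, Fb + seq_len(Fb), ] <- b2b$out
  sc <- maxpool2_forward(stem$out)          # shortcut, parameter-free
  res <- conc + sc$y
  pp <- maxpool2_forward(res)
  bnp <- bn_forward(pp$y, params$post_gamma, params$post_beta, training,
                    bnStats$post_mean, bnStats$post_var, cfg$bnEps)
  post <- bnp$y
  if (training && !is.null(masks)) post <- post * masks$post
  ls <- lstm_forward(post, params$lstm_Wx, params$lstm_Wh, params$lstm_b)
  h <- ls$h
  if (training && !is.null(masks)) h <- h * masks$lstm
  out <- as.numeric(h %*% params$dense_W) + params$dense_b
  cache <- list(stem = stem$cache, b1a = b1a$cache, b1b = b1b$cache,
                b2a = b2a$cache, b2b = b2b$cache,
                scIdx = sc$idx, stemOutDim = dim(stem$out),
                ppIdx = pp$idx, resDim = dim(res),
                postXhat = bnp$xhat, postVar = bnp$var,
                postIn = post, lstm = ls, h = h, masks = masks)
  stats <- list(stem = stem$stats, b1c1 = b1a$stats, b1c2 = b1b$stats,
                b2c1 = b2a$stats, b2c2 = b2b$stats,
                post = list(mean = bnp$mean, var = bnp$var))
  list(out = out, cache = cache, stats = stats)
}

# Full backward pass; dout is dLoss/dOutput, length B.
nnBackward <- function(params, cfg, cache, dout) {
  Fb <- cfg$branchFilters
  masks <- cache$masks
  grads <- list()
  dh <- matrix(dout, ncol = 1L) %*% t(matrix(params$dense_W, ncol = 1L))
  grads$dense_W <- t(cache$h) %*% matrix(dout, ncol = 1L)
  grads$dense_b <- sum(dout)
  if (!is.null(masks)) dh <- dh * masks$lstm
  lb <- lstm_backward(cache$postIn, params$lstm_Wx, params$lstm_Wh,
                      cache$lstm$gates, cache$lstm$hs, cache$lstm$cs, dh)
  grads$lstm_Wx <- lb$dWx; grads$lstm_Wh <- lb$dWh
  grads$lstm_b <- as.numeric(lb$db)
  dpost <- lb$dx
  if (!is.null(masks)) dpost <- dpost * masks$post
  bnb <- bn_backward(cache$postXhat, params$post_gamma, cache$postVar,
                     dpost, cfg$bnEps)
  grads$post_gamma <- as.numeric(bnb$dgamma)
  grads$post_beta <- as.numeric(bnb$dbeta)
  dres <- maxpool2_backward(cache$ppIdx, bnb$dx, cache$resDim[1L])
  # residual: gradient flows to both the concatenation and the shortcut
  d1 <- dres[, seq_len(Fb), , drop = FALSE]
  d2 <- dres[, Fb + seq_len(Fb), , drop = FALSE]
  dstem <- maxpool2_backward(cache$scIdx, dres, cache$stemOutDim[1L])
  g1b <- .convBlockBwd(d1, params, cfg, "b1c2", cache$b1b)
  g1a <- .convBlockBwd(g1b$dx, params, cfg, "b1c1", cache$b1a)
  g2b <- .convBlockBwd(d2, params, cfg, "b2c2", cache$b2b)
  g2a <- .convBlockBwd(g2b$dx, params, cfg, "b2c1", cache$b2a)
  dstem <- dstem + g1a$dx + g2a$dx
  gs <- .convBlockBwd(dstem, params, cfg, "stem", cache$stem)
  grads <- c(grads, g1b$grads, g1a$grads, g2b$grads, g2a$grads, gs$grads)
  grads$dense_W <- matrix(grads$dense_W, ncol = 1L)
  list(grads = grads, dx = gs$dx)
}

# rmsprop optimiser state and update
rmspropInit <- function(params) lapply(params, function(p) p * 0)

rmspropStep <- function(params, grads, state, lr = 1e-3, rho = 0.9,
                        eps = 1e-7) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# Update BN running statistics from one batch
nnUpdateBN <- function(bnStats, stats, momentum) {
  for (nm in names(stats)) {
    bnStats[[paste0(nm, "_mean")]] <-
      momentum * bnStats[[paste0(nm, "_mean")]] +
      (1 - momentum) * as.numeric(stats[[nm]]$mean)
    bnStats[[paste0(nm, "_var")]] <-
      momentum * bnStats[[paste0(nm, "_var")]] +
      (1 - momentum) * as.numeric(stats[[nm]]$var)
  }
  bnStats
}

# Evaluation-mode forward in chunks; X is L x 4 x B, returns length-B
# vector of raw outputs.
nnPredict <- function(params, bnStats, cfg, X, chunk = 1024L) {
  B <- dim(X)[3L]
  out <- numeric(B)
  i <- 1L
  while (i <= B) {
    j <- min(B, i + chunk - 1L)
    out[i:j] <- nnForward(params, bnStats, cfg,
                          X[, , i:j, drop = FALSE])$out
    i <- j + 1L
  }
  out
}
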