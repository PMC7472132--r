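# Redundant convolutional encoder-decoder (R-CED) for spectral-magnitude
# regression, implemented from scratch: 1-D convolutions along the frequency
# axis (im2col + BLAS matrix products), batch normalization, ReLU, and
# backpropagation with stochastic gradient descent with momentum.
#
# A batch is held as an array (channels, length, batch). The network input is
# the 8-frame magnitude context (8 channels over 129 frequency bins); the
# output is a single 129-bin frame. "Same" zero padding keeps the frequency
# dimension at 129 through all blocks -- no pooling or upsampling.

#' R-CED architecture configuration
#'
#' Sixteen convolutional blocks: blocks 1-15 are convolution + batch
#' normalization + ReLU, block 16 a bare convolution producing one output
#' channel. The default filter schedule follows the redundancy principle of
#' encoder-decoder denoisers (filter counts swell and shrink symmetrically)
#' and is an engineering choice, fully configurable.
#'
#' @param filter_counts integer vector of output channels per block; the last
#'   entry must be 1.
#' @param kernel_widths odd integer vector of kernel sizes along frequency,
#'   same length as `filter_counts`.
#' @param n_bins frequency bins per frame (default 129).
#' @param context_k input context length in frames (default 8), i.e. the
#'   number of input channels of block 1.
#' @return an object of class `rced_config`.
#' @export
rced_config <- function(filter_counts = c(12, 16, 20, 24, 32, 24, 20, 16,
                                          12, 16, 20, 24, 32, 24, 20, 1),
                        kernel_widths = c(13, 11, 9, 7, 7, 7, 9, 11,
                                          13, 11, 9, 7, 7, 9, 11, 13),
                        n_bins = 129L, context_k = 8L) {
  filter_counts <- as.integer(filter_counts)
  kernel_widths <- as.integer(kernel_widths)
  if (length(filter_counts) != length(kernel_widths)) {
    stop("`filter_counts` and `kernel_widths` must have the same length",
         call. = FALSE)
  }
  if (length(filter_counts) < 1L || any(filter_counts < 1L)) {
    stop("`filter_counts` must be positive integers", call. = FALSE)
  }
  if (filter_counts[length(filter_counts)] != 1L) {
    stop("the final block must produce exactly 1 output channel", call. = FALSE)
  }
  if (any(kernel_widths < 1L) || any(kernel_widths %% 2L == 0L)) {
    stop("`kernel_widths` must be odd positive integers (same padding)",
         call. = FALSE)
  }
  structure(
    list(n_blocks = length(filter_counts), filter_counts = filter_counts,
         kernel_widths = kernel_widths, n_bins = as.integer(n_bins),
         context_k = as.integer(context_k)),
    class = "rced_config"
  )
}

#' Training configuration for the R-CED
#'
#' Defaults follow the training recipe used throughout the package:
#' stochastic gradient descent with momentum, mini-batch size 128, 12 epochs,
#' learning rate multiplied by 0.95 after every epoch. The initial learning
#' rate and momentum are conventional SGDM values.
#'
#' @param lr0 initial learning rate.
#' @param momentum momentum coefficient.
#' @param lr_decay_per_epoch multiplicative learning-rate decay per epoch.
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs (>= 1).
#' @param seed integer seed controlling shuffling (and, through
#'   [build_rced()], weight initialization when reused there).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.01, momentum = 0.9, lr_decay_per_epoch = 0.95,
                         batch_size = 128L, epochs = 12L, seed = 1L) {
  stopifnot_scalar(lr0, "lr0", positive = TRUE)
  stopifnot_scalar(momentum, "momentum")
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)", call. = FALSE)
  stopifnot_scalar(lr_decay_per_epoch, "lr_decay_per_epoch")
  if (lr_decay_per_epoch <= 0 || lr_decay_per_epoch > 1) {
    stop("`lr_decay_per_epoch` must be in (0, 1]", call. = FALSE)
  }
  batch_size <- as.integer(batch_size); epochs <- as.integer(epochs)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  structure(
    list(lr0 = lr0, momentum = momentum,
         lr_decay_per_epoch = lr_decay_per_epoch,
         batch_size = batch_size, epochs = epochs, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build an untrained R-CED network
#'
#' Weights are initialized from a fan-in-scaled uniform distribution,
#' deterministically per seed. Batch-normalization scale/offset start at
#' 1/0 with zeroed running statistics.
#'
#' @param cfg an [rced_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `rced_model` (untrained; `$trained` is FALSE).
#' @export
build_rced <- function(cfg = rced_config(), seed = 1L) {
  if (!inherits(cfg, "rced_config")) {
    stop("`cfg` must be created by rced_config()", call. = FALSE)
  }
  c_in <- cfg$context_k
  with_seed(seed, {
    blocks <- vector("list", cfg$n_blocks)
    for (i in seq_len(cfg$n_blocks)) {
      c_out <- cfg$filter_counts[i]
      k <- cfg$kernel_widths[i]
      bound <- sqrt(1 / (c_in * k))
      blk <- list(
        W = matrix(stats::runif(c_out * c_in * k, -bound, bound),
                   nrow = c_out),
        b = numeric(c_out),
        c_in = c_in, c_out = c_out, k = k, pad = (k - 1L) %/% 2L,
        has_bn = i < cfg$n_blocks
      )
      if (blk$has_bn) {
        blk$gamma <- rep(1, c_out)
        blk$beta <- numeric(c_out)
        blk$run_mean <- numeric(c_out)
        blk$run_var <- rep(1, c_out)
      }
      blocks[[i]] <- blk
      c_in <- c_out
    }
    structure(
      list(config = cfg, blocks = blocks, trained = FALSE,
           history = numeric(0), norm_stats = NULL, init_seed = seed),
      class = "rced_model"
    )
  })
}

#' Number of learnable parameters of an R-CED
#'
#' Closed form from the schedule: for each block `c_in * c_out * k + c_out`
#' convolution parameters, plus `2 * c_out` batch-norm scale/offset for all
#' but the last block.
#'
#' @param x an `rced_model` or `rced_config`.
#' @return integer parameter count.
#' @export
n_params <- function(x) {
  cfg <- if (inherits(x, "rced_model")) x$config else x
  if (!inherits(cfg, "rced_config")) stop("not an R-CED model or config", call. = FALSE)
  c_in <- cfg$context_k
  total <- 0L
  for (i in seq_len(cfg$n_blocks)) {
    c_out <- cfg$filter_counts[i]
    total <- total + c_in * c_out * cfg$kernel_widths[i] + c_out
    if (i < cfg$n_blocks) total <- total + 2L * c_out
    c_in <- c_out
  }
  as.integer(total)
}

# learning rate of epoch e (1-based): lr0 decayed once per completed epoch
lr_at_epoch <- function(tc, e) {
  tc$lr0 * tc$lr_decay_per_epoch^(e - 1L)
}

# ---- convolution primitives -------------------------------------------------

# im2col: X (c_in, L, N) -> matrix (c_in * k, L * N) with zero "same" padding
im2col <- function(X, k, pad) {
  d <- dim(X); c_in <- d[1]; L <- d[2]; N <- d[3]
  Xp <- array(0, dim = c(c_in, L + 2L * pad, N))
  Xp[, (pad + 1L):(pad + L), ] <- X
  pos <- as.vector(outer(seq_len(L), 0:(k - 1L), `+`))   # L*k positions
  A <- Xp[, pos, , drop = FALSE]                          # (c_in, L*k, N)
  dim(A) <- c(c_in, L, k, N)
  A <- aperm(A, c(1L, 3L, 2L, 4L))                        # (c_in, k, L, N)
  dim(A) <- c(c_in * k, L * N)
  A
}

# adjoint of im2col: dXcol (c_in * k, L * N) -> dX (c_in, L, N)
col2im <- function(dXcol, c_in, k, pad, L, N) {
  dim(dXcol) <- c(c_in, k, L, N)
  dXp <- array(0, dim = c(c_in, L + 2L * pad, N))
  for (j in seq_len(k)) {
    at <- j:(j + L - 1L)
    dXp[, at, ] <- dXp[, at, ] + dXcol[, j, , ]
  }
  dXp[, (pad + 1L):(pad + L), , drop = FALSE]
}

conv_forward <- function(X, blk) {
  d <- dim(X); L <- d[2]; N <- d[3]
  Xcol <- im2col(X, blk$k, blk$pad)
  Y <- blk$W %*% Xcol + blk$b
  dim(Y) <- c(blk$c_out, L, N)
  list(Y = Y, Xcol = Xcol, L = L, N = N)
}

conv_backward <- function(dY, cache, blk) {
  L <- cache$L; N <- cache$N
  dYm <- dY
  dim(dYm) <- c(blk$c_out, L * N)
  dW <- dYm %*% t(cache$Xcol)
  db <- rowSums(dYm)
  dXcol <- crossprod(blk$W, dYm)
  dX <- col2im(dXcol, blk$c_in, blk$k, blk$pad, L, N)
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_eps <- 1e-5
bn_run_momentum <- 0.1

bn_forward <- function(X, blk, training) {
  d <- dim(X); C <- d[1]; M <- d[2] * d[3]
  Xm <- X; dim(Xm) <- c(C, M)
  if (training) {
    mu <- rowMeans(Xm)
    va <- rowMeans(Xm^2) - mu^2
  } else {
    mu <- blk$run_mean
    va <- blk$run_var
  }
  inv_sd <- 1 / sqrt(va + bn_eps)
  xhat <- (Xm - mu) * inv_sd
  Y <- blk$gamma * xhat + blk$beta
  dim(Y) <- d
  list(Y = Y, xhat = xhat, inv_sd = inv_sd, mu = mu, va = va, dims = d)
}

bn_backward <- function(dY, cache, blk) {
  d <- cache$dims; C <- d[1]; M <- d[2] * d[3]
  dYm <- dY; dim(dYm) <- c(C, M)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * blk$gamma
  # standard batch-norm gradient, vectorized per channel
  dX <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv_sd
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward over the whole network ------------------------------

rced_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    blk <- model$blocks[[i]]
    cv <- conv_forward(X, blk)
    X <- cv$Y
    cache <- list(conv = cv)
    if (blk$has_bn) {
      bn <- bn_forward(X, blk, training)
      X <- bn$Y
      relu_mask <- X > 0
      X <- X * relu_mask
      cache$bn <- bn
      cache$relu <- relu_mask
    }
    caches[[i]] <- cache
  }
  list(out = X, caches = caches)
}

rced_backward <- function(model, dY, caches) {
  grads <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[i]]
    cache <- caches[[i]]
    if (blk$has_bn) {
      dY <- dY * cache$relu
      bb <- bn_backward(dY, cache$bn, blk)
      dY <- bb$dX
      g <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
    } else {
      g <- list()
    }
    cb <- conv_backward(dY, cache$conv, blk)
    g$dW <- cb$dW; g$db <- cb$db
    grads[[i]] <- g
    dY <- cb$dX
  }
  grads
}

# feature_stack / array -> network input array (k, n_bins, n_stacks)
stacks_to_input <- function(predictors) {
  if (inherits(predictors, "feature_stack")) predictors <- predictors$stacks
  if (length(dim(predictors)) != 3L) {
    stop("predictors must be a feature_stack or an (n, bins, k) array",
         call. = FALSE)
  }
  aperm(predictors, c(3L, 2L, 1L))
}

#' Train an R-CED by backpropagation with SGD-momentum
#'
#' Minimizes mean squared error between predicted and target normalized
#' magnitude frames. The learning rate at epoch e is
#' `lr0 * lr_decay_per_epoch^(e - 1)`; shuffling is deterministic per seed.
#' Batch-normalization running statistics are accumulated for inference.
#'
#' @param model an untrained (or previously trained) `rced_model`.
#' @param predictors a [stack_context()] feature stack, or an array
#'   (n_stacks, n_bins, k), of normalized noisy magnitudes.
#' @param targets matrix (n_stacks x n_bins) of normalized clean magnitude
#'   frames, row-aligned with `predictors`.
#' @param tc a [train_config()].
#' @param norm_stats optional list with elements `predictor` and `target`
#'   ([fit_normalizer()] objects) stored in the returned model for use at
#'   inference time.
#' @return the trained `rced_model` with `$history` holding the mean training
#'   loss of each epoch.
#' @export
train_rced <- function(model, predictors, targets, tc = train_config(),
                       norm_stats = NULL) {
  if (!inherits(model, "rced_model")) stop("`model` must be an rced_model", call. = FALSE)
  if (!inherits(tc, "train_config")) stop("`tc` must be a train_config", call. = FALSE)
  X_all <- stacks_to_input(predictors)
  targets <- as.matrix(targets)
  n <- dim(X_all)[3]
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (nrow(targets) != n) {
    stop(sprintf("predictors (%d) and targets (%d) are not aligned", n,
                 nrow(targets)), call. = FALSE)
  }
  if (ncol(targets) != model$config$n_bins) {
    stop("target frame width does not match the configured bin count", call. = FALSE)
  }
  Tm <- t(targets)                       # (n_bins, n)
  vel <- lapply(model$blocks, function(blk) {
    v <- list(W = blk$W * 0, b = blk$b * 0)
    if (blk$has_bn) { v$gamma <- blk$gamma * 0; v$beta <- blk$beta * 0 }
    v
  })
  perms <- with_seed(tc$seed, lapply(seq_len(tc$epochs), function(e) sample.int(n)))
  history <- numeric(tc$epochs)
  for (e in seq_len(tc$epochs)) {
    lr <- lr_at_epoch(tc, e)
    ord <- perms[[e]]
    starts <- seq(1L, n, by = tc$batch_size)
    losses <- numeric(length(starts))
    wts <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + tc$batch_size - 1L, n)]
      Xb <- X_all[, , idx, drop = FALSE]
      Tb <- Tm[, idx, drop = FALSE]
      fw <- rced_forward(model, Xb, training = TRUE)
      Yb <- fw$out                       # (1, n_bins, |idx|)
      dim(Yb) <- dim(Tb)
      resid <- Yb - Tb
      losses[bi] <- mean(resid^2)
      wts[bi] <- length(idx)
      dY <- 2 * resid / length(resid)
      dim(dY) <- c(1L, nrow(Tb), ncol(Tb))
      grads <- rced_backward(model, dY, fw$caches)
      for (i in seq_along(model$blocks)) {
        blk <- model$blocks[[i]]
        g <- grads[[i]]
        vel[[i]]$W <- tc$momentum * vel[[i]]$W - lr * g$dW
        vel[[i]]$b <- tc$momentum * vel[[i]]$b - lr * g$db
        blk$W <- blk$W + vel[[i]]$W
        blk$b <- blk$b + vel[[i]]$b
        if (blk$has_bn) {
          vel[[i]]$gamma <- tc$momentum * vel[[i]]$gamma - lr * g$dgamma
          vel[[i]]$beta <- tc$momentum * vel[[i]]$beta - lr * g$dbeta
          blk$gamma <- blk$gamma + vel[[i]]$gamma
          blk$beta <- blk$beta + vel[[i]]$beta
          bn <- fw$caches[[i]]$bn
          blk$run_mean <- (1 - bn_run_momentum) * blk$run_mean +
            bn_run_momentum * bn$mu
          blk$run_var <- (1 - bn_run_momentum) * blk$run_var +
            bn_run_momentum * bn$va
        }
        model$blocks[[i]] <- blk
      }
    }
    history[e] <- sum(losses * wts) / sum(wts)
  }
  model$trained <- TRUE
  model$history <- history
  model$train_config <- tc
  if (!is.null(norm_stats)) model$norm_stats <- norm_stats
  model
}

#' Predict denoised normalized magnitude frames
#'
#' Runs the network in inference mode (batch normalization uses its running
#' statistics, so the output is deterministic and batch-size independent).
#'
#' @param object an `rced_model`.
#' @param stacks a feature stack or (n, bins, k) array of normalized noisy
#'   magnitude contexts.
#' @param ... unused.
#' @return matrix (n_stacks x n_bins) of predicted normalized magnitudes,
#'   row order preserved.
#' @export
predict.rced_model <- function(object, stacks, ...) {
  X <- stacks_to_input(stacks)
  fw <- rced_forward(object, X, training = FALSE)
  out <- fw$out                          # (1, n_bins, n)
  d <- dim(out)
  dim(out) <- c(d[2], d[3])
  t(out)
}

#' @export
print.rced_model <- function(x, ...) {
  cat(sprintf("<rced_model> %d blocks, %d parameters, %s\n",
              x$config$n_blocks, n_params(x),
              if (x$trained) sprintf("trained (%d epochs, final loss %.4g)",
                                     length(x$history),
                                     x$history[length(x$history)])
              else "untrained"))
  invisible(x)
}
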