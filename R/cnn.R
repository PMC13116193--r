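#' CNN model configuration
#'
#' Architecture of the gait-recognition network: two sequential
#' convolutional layers with 2 x 1 kernels and channel depths increasing
#' from 16 to 32, each followed by batch normalisation and a ReLU; one
#' max-pooling layer (2 x 2, stride 2) to reduce dimensionality; a fully
#' connected layer mapping the features to the 7 gait classes; and a
#' softmax output. The 2 x 1 kernel convolves along the sensor-channel
#' axis by default; `axis_swap = TRUE` presents samples transposed so it
#' convolves along time instead.
#'
#' @param conv_channels Feature depths of the two conv layers.
#' @param kernel Kernel extent along the convolved axis.
#' @param pool Max-pool size (and stride).
#' @param n_class Number of output classes.
#' @param axis_swap Transpose the (channels x frames) input.
#' @param bn_momentum,bn_eps Batch-normalisation running-average momentum
#'   and variance floor.
#' @return List of class `model_config`.
#' @export
model_config <- function(conv_channels = c(16L, 32L), kernel = 2L,
                         pool = 2L, n_class = 7L, axis_swap = FALSE,
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  stopifnot(length(conv_channels) == 2L,
            conv_channels[2] > conv_channels[1],
            kernel >= 1, pool >= 1, n_class >= 2)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 n_class = as.integer(n_class), axis_swap = axis_swap,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "model_config")
}

#' Training configuration
#'
#' Optimisation hyperparameters (unreported for the original model; these
#' are package defaults): Adam with step size 1e-3, batch size 16, 200
#' epochs, fixed seed, early stopping off.
#'
#' @param epochs Number of passes over the training split.
#' @param step_size Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Seed for shuffling (initialisation is seeded in
#'   [build_model()]).
#' @param early_stop_loss Stop when the epoch training loss falls below
#'   this value; `NULL` (default) disables early stopping.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 200L, step_size = 1e-3,
                         batch_size = 16L, seed = 42L,
                         early_stop_loss = NULL) {
  stopifnot(epochs >= 0, step_size > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), step_size = step_size,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_loss = early_stop_loss),
            class = "train_config")
}

#' Build a seeded gait-recognition CNN
#'
#' Allocates and initialises all parameters (He-scaled Gaussian weights,
#' unit batch-norm gains) for the given input shape. Two builds with the
#' same seed and shapes produce identical parameters.
#'
#' @param cfg A [model_config()].
#' @param input_shape `c(channels, frames)` of one sample (after any
#'   axis swap).
#' @param seed Initialisation seed.
#' @return Object of class `gait_cnn`.
#' @export
build_model <- function(cfg = model_config(), input_shape, seed = 42L) {
  stopifnot(inherits(cfg, "model_config"), length(input_shape) == 2L)
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  if (cfg$axis_swap) { tmp <- H; H <- W; W <- tmp }
  k <- cfg$kernel
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  H1 <- H - k + 1L
  H2 <- H1 - k + 1L
  if (H2 < 1L) stop("input too small along the convolved axis (", H, ")")
  Hp <- H2 %/% cfg$pool; Wp <- W %/% cfg$pool
  if (Hp < 1L || Wp < 1L) stop("input too small for the pooling layer")
  nfeat <- Hp * Wp * c2

  set.seed(seed)
  he <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- list(
    W1 = he(k * 1L, c1, k),           b1 = numeric(c1),
    g1 = rep(1, c1),                  beta1 = numeric(c1),
    W2 = he(k * c1, c2, k * c1),      b2 = numeric(c2),
    g2 = rep(1, c2),                  beta2 = numeric(c2),
    Wfc = he(nfeat, cfg$n_class, nfeat), bfc = numeric(cfg$n_class)
  )
  structure(list(
    cfg = cfg,
    input_shape = c(H, W),
    dims = list(H = H, W = W, H1 = H1, H2 = H2, Hp = Hp, Wp = Wp,
                nfeat = nfeat),
    params = params,
    bn = list(mean1 = numeric(c1), var1 = rep(1, c1),
              mean2 = numeric(c2), var2 = rep(1, c2)),
    seed = as.integer(seed),
    classes = NULL,
    preproc = NULL
  ), class = "gait_cnn")
}

# ---- vectorised forward / backward -------------------------------------
#
# Internal tensor layout is channel-first: activations are arrays of
# dimension (C, N, W, H), where H is the convolved axis (sensor channels
# by default), W the untouched axis (frames) and N the batch. Per-channel
# affine operations then reduce to vector recycling down the rows, and the
# convolution's im2col slices the contiguous last dimension.

# X: array (C, N, W, H); kernel k along H; Wmat (k*C x Cout) with row
# blocks ordered tap-major (tap 1 channels, then tap 2 channels, ...)
conv_fwd <- function(X, Wmat, b, k) {
  d <- dim(X); C <- d[1]; N <- d[2]; W <- d[3]; H <- d[4]
  H1 <- H - k + 1L
  n <- N * W * H1
  taps <- vector("list", k)
  for (t in seq_len(k)) {
    blk <- X[, , , t:(t + H1 - 1L), drop = FALSE]
    dim(blk) <- c(C, n)
    taps[[t]] <- blk
  }
  M <- do.call(rbind, taps)              # (k*C x n)
  out <- crossprod(Wmat, M) + b          # (Cout x n), bias by recycling
  dim(out) <- c(ncol(Wmat), N, W, H1)
  list(out = out, M = M)
}

conv_bwd <- function(dOut, M, Wmat, k, dimX) {
  C <- dimX[1]; N <- dimX[2]; W <- dimX[3]; H <- dimX[4]
  H1 <- H - k + 1L
  Cout <- dim(dOut)[1]
  dOut_mat <- dOut
  dim(dOut_mat) <- c(Cout, N * W * H1)
  dW <- tcrossprod(M, dOut_mat)          # (k*C x Cout)
  db <- rowSums(dOut_mat)
  dM <- Wmat %*% dOut_mat                # (k*C x n)
  dX <- array(0, dimX)
  for (t in seq_len(k)) {
    blk <- dM[((t - 1L) * C + 1L):(t * C), , drop = FALSE]
    dim(blk) <- c(C, N, W, H1)
    dX[, , , t:(t + H1 - 1L)] <- dX[, , , t:(t + H1 - 1L), drop = FALSE] + blk
  }
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, g, beta, eps, training, run_mean, run_var,
                   momentum) {
  d <- dim(X)
  C <- d[1]
  Xm <- X
  dim(Xm) <- c(C, prod(d[-1]))
  if (training) {
    mu <- rowMeans(Xm)
    xc <- Xm - mu
    v <- rowMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- Xm - mu
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  y <- g * xhat + beta
  dim(y) <- d
  list(out = y, xhat = xhat, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dOut, cache, g) {
  d <- dim(dOut)
  C <- d[1]
  dY <- dOut
  dim(dY) <- c(C, prod(d[-1]))
  n <- ncol(dY)
  xhat <- cache$xhat
  dxhat <- g * dY
  dg <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  # dX = inv_sd/n * (n*dxhat - rowSums(dxhat) - xhat * rowSums(dxhat*xhat))
  dX <- (cache$inv_sd / n) *
    (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dX) <- d
  list(dX = dX, dg = dg, dbeta = dbeta)
}

pool_fwd <- function(X, p) {
  d <- dim(X); C <- d[1]; N <- d[2]; W <- d[3]; H <- d[4]
  Hp <- H %/% p; Wp <- W %/% p
  slices <- vector("list", p * p)
  i <- 0L
  for (dh in seq_len(p)) for (dw in seq_len(p)) {
    i <- i + 1L
    slices[[i]] <- X[, , seq(dw, by = p, length.out = Wp),
                     seq(dh, by = p, length.out = Hp), drop = FALSE]
  }
  out <- slices[[1]]
  for (i in seq_len(p * p)[-1]) out <- pmax(out, slices[[i]])
  list(out = out, slices = slices)
}

pool_bwd <- function(dOut, cache, p, dimX) {
  out <- cache$out
  C <- dimX[1]; N <- dimX[2]; W <- dimX[3]; H <- dimX[4]
  Hp <- H %/% p; Wp <- W %/% p
  dX <- array(0, dimX)
  taken <- array(FALSE, dim(out))
  i <- 0L
  for (dh in seq_len(p)) for (dw in seq_len(p)) {
    i <- i + 1L
    hit <- (cache$slices[[i]] == out) & !taken  # first-match tie-break
    taken <- taken | hit
    dX[, , seq(dw, by = p, length.out = Wp),
       seq(dh, by = p, length.out = Hp)] <- dOut * hit
  }
  dX
}

softmax_rows <- function(z) {
  m <- z[, 1L]
  for (j in seq_len(ncol(z))[-1]) m <- pmax(m, z[, j])
  e <- exp(z - m)
  e / rowSums(e)
}

# flatten pooled activations (C, N, Wp, Hp) to (N x nfeat); feature order
# is channel-fastest, then pooled frame, then pooled row — Wfc rows follow
# the same order
pool_flatten <- function(act) {
  d <- dim(act)
  F <- aperm(act, c(1L, 3L, 4L, 2L))
  dim(F) <- c(d[1] * d[3] * d[4], d[2])
  t(F)
}

# full forward pass; X (N, H, W) raw input array
cnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  d <- dim(X)
  X4 <- aperm(X, c(1L, 3L, 2L))          # (N, W, H)
  dim(X4) <- c(1L, d[1], d[3], d[2])     # (C=1, N, W, H)
  c1f <- conv_fwd(X4, p$W1, p$b1, cfg$kernel)
  bn1 <- bn_fwd(c1f$out, p$g1, p$beta1, cfg$bn_eps, training,
                model$bn$mean1, model$bn$var1, cfg$bn_momentum)
  r1 <- bn1$out; r1[r1 < 0] <- 0
  c2f <- conv_fwd(r1, p$W2, p$b2, cfg$kernel)
  bn2 <- bn_fwd(c2f$out, p$g2, p$beta2, cfg$bn_eps, training,
                model$bn$mean2, model$bn$var2, cfg$bn_momentum)
  r2 <- bn2$out; r2[r2 < 0] <- 0
  pl <- pool_fwd(r2, cfg$pool)
  Xf <- pool_flatten(pl$out)
  logits <- Xf %*% p$Wfc
  logits <- logits + rep(p$bfc, each = nrow(logits))
  probs <- softmax_rows(logits)
  res <- list(probs = probs, logits = logits)
  if (training) res$bn_updates <- list(mean1 = bn1$run_mean,
                                       var1 = bn1$run_var,
                                       mean2 = bn2$run_mean,
                                       var2 = bn2$run_var)
  if (keep_cache)
    res$cache <- list(X4 = X4, c1f = c1f, bn1 = bn1, r1 = r1,
                      c2f = c2f, bn2 = bn2, r2 = r2, pl = pl, Xf = Xf)
  res
}

# backward pass from softmax cross-entropy; Y one-hot (N x n_class)
cnn_backward <- function(model, fwd, Y) {
  cfg <- model$cfg; p <- model$params
  cache <- fwd$cache
  N <- nrow(Y)
  dlogits <- (fwd$probs - Y) / N
  dWfc <- crossprod(cache$Xf, dlogits)
  dbfc <- colSums(dlogits)
  dF <- p$Wfc %*% t(dlogits)             # (nfeat x N)
  dpool <- dF
  dp <- dim(cache$pl$out)                # (C, N, Wp, Hp)
  dim(dpool) <- c(dp[1], dp[3], dp[4], dp[2])
  dpool <- aperm(dpool, c(1L, 4L, 2L, 3L))
  dr2 <- pool_bwd(dpool, cache$pl, cfg$pool, dim(cache$r2))
  dr2[cache$bn2$out <= 0] <- 0
  bn2b <- bn_bwd(dr2, cache$bn2, p$g2)
  c2b <- conv_bwd(bn2b$dX, cache$c2f$M, p$W2, cfg$kernel, dim(cache$r1))
  dr1 <- c2b$dX
  dr1[cache$bn1$out <= 0] <- 0
  bn1b <- bn_bwd(dr1, cache$bn1, p$g1)
  c1b <- conv_bwd(bn1b$dX, cache$c1f$M, p$W1, cfg$kernel,
                  dim(cache$X4))
  list(W1 = c1b$dW, b1 = c1b$db, g1 = bn1b$dg, beta1 = bn1b$dbeta,
       W2 = c2b$dW, b2 = c2b$db, g2 = bn2b$dg, beta2 = bn2b$dbeta,
       Wfc = dWfc, bfc = dbfc)
}

# ---- user-facing operations --------------------------------------------

# coerce a gait_sample / matrix into the model's (H, W) orientation
sample_to_input <- function(model, sample) {
  x <- if (inherits(sample, "gait_sample")) t(sample$channels) else sample
  if (!is.matrix(x)) stop("sample must be a gait_sample or a matrix")
  if (model$cfg$axis_swap) x <- t(x)
  if (!identical(dim(x), as.integer(model$input_shape)))
    stop(sprintf("sample shape (%d x %d) does not match model input (%d x %d)",
                 nrow(x), ncol(x), model$input_shape[1],
                 model$input_shape[2]))
  x
}

#' Forward pass: class probabilities for one sample
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns the softmax probability distribution over the gait classes.
#'
#' @param model A `gait_cnn`.
#' @param sample A `gait_sample` (channels as frames x channels) or a
#'   matrix already in (channels x frames) orientation, on the scale the
#'   model was trained on.
#' @return Numeric probability vector (non-negative, sums to 1).
#' @export
forward <- function(model, sample) {
  stopifnot(inherits(model, "gait_cnn"))
  x <- sample_to_input(model, sample)
  X <- array(x, c(1L, dim(x)))
  p <- drop(cnn_forward(model, X)$probs)
  names(p) <- model$classes %||% NULL
  p
}

#' Predicted class index with lowest-index tie-break
#' @param probs Probability vector.
#' @return Integer index of the predicted class.
#' @export
argmax_class <- function(probs) which.max(probs)

# dataset -> (X array (N,H,W), y integer labels, class order)
dataset_tensors <- function(dataset, model, split = NULL) {
  idx <- seq_along(dataset$samples)
  if (!is.null(split)) {
    if (is.null(dataset$split)) stop("dataset has no split assignment")
    idx <- which(dataset$split == split)
  }
  if (!length(idx)) stop("no samples in requested split")
  classes <- if (all(dataset$classes %in% gait_labels()))
    gait_labels()[gait_labels() %in% dataset$classes]
  else dataset$classes
  first <- sample_to_input(model, dataset$samples[[idx[1]]])
  X <- array(0, c(length(idx), dim(first)))
  y <- integer(length(idx))
  for (i in seq_along(idx)) {
    s <- dataset$samples[[idx[i]]]
    X[i, , ] <- sample_to_input(model, s)
    y[i] <- match(s$label, classes)
  }
  if (anyNA(y)) stop("sample label not in the dataset class list")
  list(X = X, y = y, classes = classes)
}

#' Train the CNN
#'
#' Mini-batch Adam on softmax cross-entropy over the dataset's train
#' split. The per-epoch history reports the mean training-mode batch loss
#' and accuracy; the returned `final_train_accuracy` is a single
#' inference-mode pass over the train split after the last epoch. The run
#' is seeded end to end; a diverging loss (NaN) raises an error carrying
#' the last finite state. The fitted preprocessing of the dataset
#' (retained channels, normalisation, class order) is stored on the model
#' for streaming reuse.
#'
#' @param model A `gait_cnn` from [build_model()].
#' @param dataset A split (and usually normalised) `gait_dataset`.
#' @param cfg A [train_config()].
#' @param labels Optional integer label override (same length as the
#'   train split), used e.g. for permutation controls.
#' @return The trained model, with `$history` (data frame epoch, loss,
#'   accuracy) and `$final_train_accuracy`.
#' @export
train_cnn <- function(model, dataset, cfg = train_config(),
                      labels = NULL) {
  stopifnot(inherits(model, "gait_cnn"), inherits(dataset, "gait_dataset"),
            inherits(cfg, "train_config"))
  tens <- dataset_tensors(dataset, model, split = "train")
  X <- tens$X
  y <- if (is.null(labels)) tens$y else as.integer(labels)
  stopifnot(length(y) == dim(X)[1])
  N <- dim(X)[1]
  nc <- model$cfg$n_class
  Y <- matrix(0, N, nc); Y[cbind(seq_len(N), y)] <- 1

  model$classes <- tens$classes
  model$preproc <- list(
    retained_channels = dataset$retained_channels,
    norm = dataset$norm,
    window_frames = model$input_shape[if (model$cfg$axis_swap) 1 else 2]
  )
  if (cfg$epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), loss = numeric(0),
                                accuracy = numeric(0))
    return(model)
  }

  # Adam state
  adam <- lapply(model$params, function(p) list(m = p * 0, v = p * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_correct <- 0L
    for (b0 in seq(1L, N, by = cfg$batch_size)) {
      bi <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
      Xb <- X[bi, , , drop = FALSE]
      Yb <- Y[bi, , drop = FALSE]
      fwd <- cnn_forward(model, Xb, training = TRUE, keep_cache = TRUE)
      model$bn <- fwd$bn_updates
      pr <- fwd$probs
      loss <- -mean(log(pmax(pr[cbind(seq_along(bi), y[bi])], 1e-12)))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      ep_loss <- ep_loss + loss * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(pr, ties.method = "first") == y[bi])
      grads <- cnn_backward(model, fwd, Yb)
      t_step <- t_step + 1L
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * g
        adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * g^2
        mhat <- adam[[nm]]$m / (1 - b1^t_step)
        vhat <- adam[[nm]]$v / (1 - b2^t_step)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$step_size * mhat / (sqrt(vhat) + eps)
      }
    }
    history$loss[ep] <- ep_loss / N
    history$accuracy[ep] <- ep_correct / N
    if (!is.null(cfg$early_stop_loss) &&
        history$loss[ep] < cfg$early_stop_loss) {
      history <- history[seq_len(ep), ]
      break
    }
  }
  model$history <- history
  final <- cnn_forward(model, X)$probs
  model$final_train_accuracy <-
    mean(max.col(final, ties.method = "first") == y)
  model
}

#' Evaluate the CNN on a dataset split
#'
#' @param model A trained `gait_cnn`.
#' @param dataset A `gait_dataset`.
#' @param split `"test"` (default), `"train"`, or `NULL` for all samples.
#' @return Object of class `eval_result`: `confusion` (true classes in
#'   rows), `accuracy`, `per_class_recall` (`NA` for a class absent from
#'   the split), `n`.
#' @export
evaluate_cnn <- function(model, dataset, split = "test") {
  stopifnot(inherits(model, "gait_cnn"))
  tens <- dataset_tensors(dataset, model, split = split)
  probs <- cnn_forward(model, tens$X)$probs
  pred <- max.col(probs, ties.method = "first")
  nc <- length(tens$classes)
  confusion <- matrix(0L, nc, nc,
                      dimnames = list(true = tens$classes,
                                      pred = tens$classes))
  for (i in seq_along(pred))
    confusion[tens$y[i], pred[i]] <- confusion[tens$y[i], pred[i]] + 1L
  totals <- rowSums(confusion)
  recall <- ifelse(totals > 0, diag(confusion) / totals, NA_real_)
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    per_class_recall = recall,
    n = sum(confusion)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.4f on %d samples\n", x$accuracy,
              x$n))
  print(x$confusion)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON container holding the configuration, flat parameter
#' arrays, batch-norm statistics and stored preprocessing.
#'
#' @param model A `gait_cnn`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gait_cnn"))
  obj <- list(
    cfg = unclass(model$cfg),
    input_shape = model$input_shape,
    dims = model$dims,
    seed = model$seed,
    classes = model$classes,
    preproc = model$preproc,
    bn = model$bn,
    param_dims = lapply(model$params, function(p)
      if (is.matrix(p)) dim(p) else length(p)),
    params = lapply(model$params, as.numeric)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$cfg
  cfg$conv_channels <- as.integer(cfg$conv_channels)
  class(cfg) <- "model_config"
  params <- list()
  for (nm in names(obj$params)) {
    v <- as.numeric(obj$params[[nm]])
    d <- obj$param_dims[[nm]]
    params[[nm]] <- if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  }
  preproc <- obj$preproc
  if (!is.null(preproc$norm) && !is.null(preproc$norm$mean)) {
    preproc$norm$mean <- unlist(preproc$norm$mean)
    preproc$norm$sd <- unlist(preproc$norm$sd)
  }
  structure(list(
    cfg = cfg,
    input_shape = as.integer(obj$input_shape),
    dims = obj$dims,
    params = params,
    bn = lapply(obj$bn, as.numeric),
    seed = obj$seed,
    classes = obj$classes,
    preproc = preproc
  ), class = "gait_cnn")
}
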