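# Independent brute-force oracle for the CNN forward pass: plain nested
# loops over logical (H, W, C) tensors, no shared code with the package's
# vectorised implementation. Weight conventions (documented in cnn.R):
#  - conv weights W[(tap-1)*C_in + c_in, c_out], kernel along H
#  - batch norm in inference mode uses the model's running statistics
#  - max pool p x p, stride p, truncating partial blocks
#  - flatten order: channel fastest, then pooled frame (w), then pooled
#    row (h): j = c + C*((w-1) + Wp*(h-1))
naive_conv <- function(x, Wmat, b, k) {
  # x: array (H, W, C); returns (H-k+1, W, Cout)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Cout <- ncol(Wmat)
  out <- array(0, c(H - k + 1, W, Cout))
  for (h in seq_len(H - k + 1)) for (w in seq_len(W)) for (co in seq_len(Cout)) {
    acc <- b[co]
    for (t in seq_len(k)) for (ci in seq_len(C))
      acc <- acc + x[h + t - 1, w, ci] * Wmat[(t - 1) * C + ci, co]
    out[h, w, co] <- acc
  }
  out
}

naive_bn_relu <- function(x, g, beta, mean, var, eps) {
  d <- dim(x)
  out <- array(0, d)
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) for (c in seq_len(d[3])) {
    y <- g[c] * (x[h, w, c] - mean[c]) / sqrt(var[c] + eps) + beta[c]
    out[h, w, c] <- max(y, 0)
  }
  out
}

naive_pool <- function(x, p) {
  d <- dim(x)
  Hp <- d[1] %/% p; Wp <- d[2] %/% p
  out <- array(0, c(Hp, Wp, d[3]))
  for (h in seq_len(Hp)) for (w in seq_len(Wp)) for (c in seq_len(d[3])) {
    block <- x[((h - 1) * p + 1):(h * p), ((w - 1) * p + 1):(w * p), c]
    out[h, w, c] <- max(block)
  }
  out
}

naive_cnn_forward <- function(model, x) {
  # x: matrix (H, W) in the model's input orientation
  cfg <- model$cfg; p <- model$params
  a <- array(x, c(nrow(x), ncol(x), 1))
  a <- naive_conv(a, p$W1, p$b1, cfg$kernel)
  a <- naive_bn_relu(a, p$g1, p$beta1, model$bn$mean1, model$bn$var1,
                     cfg$bn_eps)
  a <- naive_conv(a, p$W2, p$b2, cfg$kernel)
  a <- naive_bn_relu(a, p$g2, p$beta2, model$bn$mean2, model$bn$var2,
                     cfg$bn_eps)
  a <- naive_pool(a, cfg$pool)
  d <- dim(a)
  feat <- numeric(d[1] * d[2] * d[3])
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) for (c in seq_len(d[3]))
    feat[c + d[3] * ((w - 1) + d[2] * (h - 1))] <- a[h, w, c]
  logits <- as.numeric(t(model$params$Wfc) %*% feat) + model$params$bfc
  e <- exp(logits - max(logits))
  e / sum(e)
}

# small randomly-parameterised model for oracle comparisons
random_tiny_model <- function(seed, H = 5, W = 6, n_class = 4) {
  cfg <- model_config(conv_channels = c(2L, 3L), n_class = n_class)
  m <- build_model(cfg, c(H, W), seed = seed)
  set.seed(seed + 10000)
  m$params <- lapply(m$params, function(p) {
    if (is.matrix(p)) matrix(rnorm(length(p)), nrow(p), ncol(p))
    else rnorm(length(p))
  })
  m$bn <- list(mean1 = rnorm(2), var1 = runif(2, 0.5, 2),
               mean2 = rnorm(3), var2 = runif(3, 0.5, 2))
  m
}
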