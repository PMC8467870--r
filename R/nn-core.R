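# Minimal seeded neural-network engine: 1D valid convolutions (C++ GEMM
# kernels), max-pooling, global average pooling, dense layers, LSTMs, a
# softmax cross-entropy head and an Adam optimizer.  Everything is plain
# R arrays so training is deterministic given the seed.

glorot <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

nn_conv_layer <- function(k, c_in, c_out) {
  list(type = "conv", k = k, c_in = c_in, c_out = c_out,
       W = glorot(k * c_in, c_out, fan_in = k * c_in, fan_out = k * c_out),
       b = numeric(c_out))
}

nn_dense_layer <- function(d_in, d_out, activation = "linear") {
  list(type = "dense", d_in = d_in, d_out = d_out, activation = activation,
       W = glorot(d_in, d_out), b = numeric(d_out))
}

nn_pool_layer <- function() list(type = "pool")
nn_gap_layer <- function() list(type = "gap")

conv_forward <- function(layer, x) {
  out <- cpp_conv1d_forward(x, layer$W, layer$b, layer$k, TRUE)
  list(out = out, cache = list(x = x, out = out))
}

conv_backward <- function(layer, cache, gout) {
  bw <- cpp_conv1d_backward(cache$x, layer$W, cache$out, gout, layer$k, TRUE)
  list(gx = bw$gx, grads = list(W = bw$gW, b = as.numeric(bw$gb)))
}

pool_forward <- function(layer, x) {
  list(out = cpp_maxpool_forward(x), cache = list(x = x))
}

pool_backward <- function(layer, cache, gout) {
  list(gx = cpp_maxpool_backward(cache$x, gout), grads = NULL)
}

gap_forward <- function(layer, x) {
  # (L, C, B) -> (C, B)
  L <- dim(x)[1]
  out <- apply(x, 3, colMeans)          # (C, B)
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(x)[2])
  list(out = out, cache = list(dim = dim(x)))
}

gap_backward <- function(layer, cache, gout) {
  d <- cache$dim
  gx <- array(rep(gout, each = d[1]) / d[1], d)
  list(gx = gx, grads = NULL)
}

dense_forward <- function(layer, x) {
  # x: (d_in, B) -> out: (d_out, B)
  z <- crossprod(layer$W, x) + layer$b
  if (layer$activation == "relu") {
    mask <- z > 0
    z[!mask] <- 0
    list(out = z, cache = list(x = x, mask = mask))
  } else {
    list(out = z, cache = list(x = x))
  }
}

dense_backward <- function(layer, cache, gout) {
  if (layer$activation == "relu") gout <- gout * cache$mask
  list(gx = layer$W %*% gout,
       grads = list(W = tcrossprod(cache$x, gout), b = rowSums(gout)))
}

# softmax over rows of logits (d_out, B) plus mean cross-entropy
softmax_probs <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

softmax_ce <- function(z, y_onehot) {
  p <- softmax_probs(z)
  B <- ncol(z)
  loss <- -mean(colSums(y_onehot * log(pmax(p, 1e-12))))
  list(loss = loss, probs = p, grad = (p - y_onehot) / B)
}

# ---- Adam ------------------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    st <- list(mW = ly$W * 0, vW = ly$W * 0,
               mb = ly$b * 0, vb = ly$b * 0)
    if (!is.null(ly$U)) { st$mU <- ly$U * 0; st$vU <- ly$U * 0 }
    st
  })
}

adam_update_param <- function(p, g, m, v, lr, t,
                              b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# apply gradients to one layer's parameters
adam_step_layer <- function(layer, grads, state, lr, t) {
  for (nm in names(grads)) {
    up <- adam_update_param(layer[[nm]], grads[[nm]],
                            state[[paste0("m", nm)]],
                            state[[paste0("v", nm)]], lr, t)
    layer[[nm]] <- up$p
    state[[paste0("m", nm)]] <- up$m
    state[[paste0("v", nm)]] <- up$v
  }
  list(layer = layer, state = state)
}

#' Training configuration for the network sub-models
#'
#' @param epochs maximum epochs (default 30).
#' @param batch_size minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience early-stopping patience on validation loss (default 5).
#' @param val_fraction fraction of the training data held out as the
#'   early-stopping validation split.
#' @param seed RNG seed for initialization and shuffling.
#' @param verbose print a one-line log per epoch.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 64L, lr = 1e-3,
                         patience = 5L, val_fraction = 0.15, seed = 1L,
                         verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}
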