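#' Specification of the band-power sequence RNN
#'
#' A bidirectional LSTM (20 hidden units per direction, concatenated to
#' 40 per step) over the 29-step, 8-feature band-power sequence, followed
#' by a unidirectional LSTM (10 hidden units, last state kept), a dense
#' ReLU layer of 32 and a softmax dense output of 2.
#'
#' @param n_steps sequence length (default 29).
#' @param n_features features per step (default 8).
#' @return list of class `rnn_spec`.
#' @export
rnn_spec <- function(n_steps = 29L, n_features = 8L) {
  structure(list(n_steps = as.integer(n_steps),
                 n_features = as.integer(n_features),
                 bi_hidden = 20L, uni_hidden = 10L, dense_dim = 32L,
                 embedding_dim = 32L, n_classes = 2L),
            class = "rnn_spec")
}

lstm_n_params <- function(d_in, h) 4L * ((d_in + h) * h + h)

#' Build the band-power RNN with its parameter census
#'
#' @param spec an [rnn_spec()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `rnn_model` with fields `trunk`
#'   (bidirectional LSTM, unidirectional LSTM, dense-32 ReLU -- the
#'   32-vector after the ReLU is the embedding tap), `head` (softmax
#'   dense) and `census`.
#' @export
build_rnn <- function(spec = rnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "rnn_spec"))
  with_seed(seed, {
    trunk <- list(
      nn_bilstm_layer(spec$n_features, spec$bi_hidden),
      nn_lstm_layer(2L * spec$bi_hidden, spec$uni_hidden),
      nn_dense_layer(spec$uni_hidden, spec$dense_dim, activation = "relu")
    )
    head_layer <- nn_dense_layer(spec$dense_dim, spec$n_classes)
    census <- data.frame(
      layer = c("Input", "Bi-LSTM", "Uni-directional LSTM", "Dense",
                "Dense (output)"),
      n_params = c(0L,
                   2L * lstm_n_params(spec$n_features, spec$bi_hidden),
                   lstm_n_params(2L * spec$bi_hidden, spec$uni_hidden),
                   spec$uni_hidden * spec$dense_dim + spec$dense_dim,
                   spec$dense_dim * spec$n_classes + spec$n_classes),
      out_x = c(spec$n_steps, spec$n_steps, spec$uni_hidden,
                spec$dense_dim, spec$n_classes),
      out_y = c(spec$n_features, 2L * spec$bi_hidden, 1L, 1L, 1L))
    structure(list(spec = spec, trunk = trunk, head = head_layer,
                   census = census, seed = as.integer(seed),
                   trained = FALSE, norm = NULL),
              class = c("rnn_model", "nn_model"))
  })
}

# forward through the recurrent trunk; X: (B, 8, 29) -> embedding (32, B)
rnn_trunk_forward <- function(trunk, X) {
  r1 <- bilstm_forward(trunk[[1]], X)
  r2 <- lstm_forward(trunk[[2]], r1$seq)
  r3 <- dense_forward(trunk[[3]], t(r2$last))
  list(emb = r3$out,
       caches = list(r1$cache, r2$cache, r3$cache,
                     dims = dim(r1$seq)))
}

rnn_trunk_backward <- function(trunk, caches, g_emb) {
  b3 <- dense_backward(trunk[[3]], caches[[3]], g_emb)
  glast <- t(b3$gx)                       # (B, 10)
  d <- caches$dims                        # (B, 40, T)
  gseq <- array(0, c(d[1], trunk[[2]]$h, d[3]))
  gseq[, , d[3]] <- glast
  b2 <- lstm_backward(trunk[[2]], caches[[2]], gseq)
  b1 <- bilstm_backward(trunk[[1]], caches[[1]], b2$gx)
  list(b1$grads, b2$grads, b3$grads)
}

# log-then-z-score standardization of band-power sequences.
# A: array (29, 8, n); stats are per feature column, fitted on training
# data (powers span decades, hence the log)
fit_band_norm <- function(A, eps = 1e-12) {
  L <- log(A + eps)
  m <- apply(L, 2, mean)
  s <- apply(L, 2, sd)
  s[s == 0] <- 1
  list(mean = m, sd = s, eps = eps)
}

apply_band_norm <- function(A, norm) {
  L <- log(A + norm$eps)
  for (j in seq_len(dim(L)[2]))
    L[, j, ] <- (L[, j, ] - norm$mean[j]) / norm$sd[j]
  L
}

# batch builder: normalized (29, 8, n) -> (B, 8, 29)
rnn_batch <- function(An, idx) {
  aperm(An[, , idx, drop = FALSE], c(3, 2, 1))
}
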