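#' Build the pre-merged CNN + RNN network
#'
#' Concatenates the CNN's 12-dimensional global-average-pooling embedding
#' with the RNN's 32-dimensional dense-ReLU embedding into a 44-vector
#' feeding a softmax dense head of 2.  The trunks are initialized from
#' the supplied (typically already trained) models; by default the merged
#' network is fine-tuned end to end, `freeze_trunks = TRUE` trains only
#' the head.
#'
#' @param cnn a `cnn_model`.
#' @param rnn an `rnn_model`.
#' @param seed RNG seed for the head initialization.
#' @param freeze_trunks keep the trunk weights fixed during training.
#' @return An object of class `premerge_model`.
#' @export
build_premerge <- function(cnn, rnn, seed = 1L, freeze_trunks = FALSE) {
  stopifnot(inherits(cnn, "cnn_model"), inherits(rnn, "rnn_model"))
  d_cnn <- cnn$spec$embedding_dim
  d_rnn <- rnn$spec$embedding_dim
  merged <- d_cnn + d_rnn
  # the head is a linear softmax classifier on the concatenated
  # embeddings; a zero start (as in logistic regression) makes its first
  # gradient steps move in the class direction regardless of seed
  head_layer <- nn_dense_layer(merged, 2L)
  head_layer$W[] <- 0
  head_layer$b[] <- 0
  census <- data.frame(
    layer = c("CNN embedding", "RNN embedding", "Pre-merge concat",
              "Dense (output)"),
    n_params = c(0L, 0L, 0L, merged * 2L + 2L),
    out_x = c(d_cnn, d_rnn, merged, 2L),
    out_y = 1L)
  structure(list(cnn_trunk = cnn$trunk, rnn_trunk = rnn$trunk,
                 head = head_layer, census = census,
                 merged_dim = merged, d_cnn = d_cnn,
                 rnn_norm = rnn$norm, freeze_trunks = isTRUE(freeze_trunks),
                 seed = as.integer(seed), trained = FALSE),
            class = c("premerge_model", "nn_model"))
}

#' @exportS3Method
nn_forward.premerge_model <- function(model, batch) {
  cf <- cnn_trunk_forward(model$cnn_trunk, batch$wave)
  rf <- rnn_trunk_forward(model$rnn_trunk, batch$band)
  emb <- rbind(cf$emb, rf$emb)            # (44, B)
  hd <- dense_forward(model$head, emb)
  list(logits = hd$out, cnn_caches = cf$caches, rnn_caches = rf$caches,
       head_cache = hd$cache)
}

#' @exportS3Method
nn_backward.premerge_model <- function(model, fw, gz) {
  hb <- dense_backward(model$head, fw$head_cache, gz)
  if (model$freeze_trunks)
    return(list(cnn = NULL, rnn = NULL, head = hb$grads))
  g_cnn <- hb$gx[seq_len(model$d_cnn), , drop = FALSE]
  g_rnn <- hb$gx[(model$d_cnn + 1L):model$merged_dim, , drop = FALSE]
  list(cnn = cnn_trunk_backward(model$cnn_trunk, fw$cnn_caches, g_cnn),
       rnn = rnn_trunk_backward(model$rnn_trunk, fw$rnn_caches, g_rnn),
       head = hb$grads)
}

#' @exportS3Method
nn_trainable.premerge_model <- function(model) {
  if (model$freeze_trunks)
    return(list(cnn = NULL, rnn = NULL, head = layer_trainable(model$head)))
  list(cnn = lapply(model$cnn_trunk, layer_trainable),
       rnn = lapply(model$rnn_trunk, layer_trainable),
       head = layer_trainable(model$head))
}

#' @exportS3Method
nn_set_trainable.premerge_model <- function(model, tr) {
  if (!is.null(tr$cnn))
    for (i in seq_along(model$cnn_trunk))
      model$cnn_trunk[[i]] <- layer_set_trainable(model$cnn_trunk[[i]],
                                                  tr$cnn[[i]])
  if (!is.null(tr$rnn))
    for (i in seq_along(model$rnn_trunk))
      model$rnn_trunk[[i]] <- layer_set_trainable(model$rnn_trunk[[i]],
                                                  tr$rnn[[i]])
  model$head <- layer_set_trainable(model$head, tr$head)
  model
}

# frozen-trunk helper: compute the 44-dim merged embeddings in batches
premerge_embeddings <- function(model, Xstd, An, batch_size = 256L) {
  n <- ncol(Xstd)
  emb <- matrix(NA_real_, model$merged_dim, n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    cf <- cnn_trunk_forward(model$cnn_trunk, cnn_batch(Xstd, idx))
    rf <- rnn_trunk_forward(model$rnn_trunk, rnn_batch(An, idx))
    emb[, idx] <- rbind(cf$emb, rf$emb)
  }
  emb
}

# internal throwaway model so the shared loop can train just the head on
# cached embeddings
#' @exportS3Method
nn_forward.dense_head_model <- function(model, batch) {
  hd <- dense_forward(model$head, batch)
  list(logits = hd$out, head_cache = hd$cache)
}
#' @exportS3Method
nn_backward.dense_head_model <- function(model, fw, gz) {
  hb <- dense_backward(model$head, fw$head_cache, gz)
  list(head = hb$grads)
}
#' @exportS3Method
nn_trainable.dense_head_model <- function(model)
  list(head = layer_trainable(model$head))
#' @exportS3Method
nn_set_trainable.dense_head_model <- function(model, tr) {
  model$head <- layer_set_trainable(model$head, tr$head)
  model
}

#' @export
train_submodel.premerge_model <- function(model, x, y,
                                          config = train_config()) {
  stopifnot(is.list(x), !is.null(x$wave), !is.null(x$band))
  y <- as.numeric(as.logical(y))
  if (is.null(model$rnn_norm)) model$rnn_norm <- fit_band_norm(x$band)
  Xstd <- standardize_waveform(x$wave)
  An <- apply_band_norm(x$band, model$rnn_norm)
  if (model$freeze_trunks) {
    # trunks fixed: one embedding pass, then train the softmax head only
    emb <- premerge_embeddings(model, Xstd, An)
    hm <- structure(list(head = model$head), class = "dense_head_model")
    hm <- net_train_loop(hm, function(idx) emb[, idx, drop = FALSE],
                         length(y), y, config)
    model$head <- hm$head
    model$trained <- TRUE
    model$history <- hm$history
    return(model)
  }
  batch_fn <- function(idx)
    list(wave = cnn_batch(Xstd, idx), band = rnn_batch(An, idx))
  net_train_loop(model, batch_fn, length(y), y, config)
}

#' @export
predict_proba.premerge_model <- function(model, x, batch_size = 256L) {
  Xstd <- standardize_waveform(x$wave)
  An <- apply_band_norm(x$band, model$rnn_norm)
  batch_fn <- function(idx)
    list(wave = cnn_batch(Xstd, idx), band = rnn_batch(An, idx))
  net_predict(model, batch_fn, ncol(x$wave), batch_size)
}
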