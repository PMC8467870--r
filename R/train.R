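# ---- trainable-parameter bookkeeping ---------------------------------

layer_trainable <- function(ly) {
  if (is.null(ly) || is.null(ly$type)) return(NULL)
  switch(ly$type,
         conv = ,
         dense = list(W = ly$W, b = ly$b),
         lstm = list(W = ly$W, U = ly$U, b = ly$b),
         bilstm = list(fwd = list(W = ly$fwd$W, U = ly$fwd$U, b = ly$fwd$b),
                       bwd = list(W = ly$bwd$W, U = ly$bwd$U, b = ly$bwd$b)),
         NULL)
}

layer_set_trainable <- function(ly, vals) {
  if (is.null(vals)) return(ly)
  if (ly$type == "bilstm") {
    for (d in c("fwd", "bwd"))
      for (nm in names(vals[[d]])) ly[[d]][[nm]] <- vals[[d]][[nm]]
  } else {
    for (nm in names(vals)) ly[[nm]] <- vals[[nm]]
  }
  ly
}

flat_leaves <- function(x, prefix = "p") {
  if (is.null(x)) return(list())
  if (is.numeric(x)) return(stats::setNames(list(x), prefix))
  out <- list()
  keys <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  for (i in seq_along(x))
    out <- c(out, flat_leaves(x[[i]], paste0(prefix, ".", keys[i])))
  out
}

unflatten_into <- function(x, flat, prefix = "p") {
  if (is.null(x)) return(x)
  if (is.numeric(x)) {
    v <- flat[[prefix]]
    attributes(v) <- attributes(x)
    return(v)
  }
  keys <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  for (i in seq_along(x))   # x[i] <- list(...) keeps NULL placeholders
    x[i] <- list(unflatten_into(x[[i]], flat, paste0(prefix, ".", keys[i])))
  x
}

#' Per-layer trainable parameter counts of a built model
#'
#' @param model a `cnn_model`, `rnn_model` or `premerge_model`.
#' @return the model's census data.frame.
#' @export
param_census <- function(model) model$census

# ---- generic forward/backward dispatch -------------------------------

nn_forward <- function(model, batch) UseMethod("nn_forward")
nn_backward <- function(model, fw, gz) UseMethod("nn_backward")
nn_trainable <- function(model) UseMethod("nn_trainable")
nn_set_trainable <- function(model, tr) UseMethod("nn_set_trainable")

#' @exportS3Method
nn_forward.cnn_model <- function(model, batch) {
  tf <- cnn_trunk_forward(model$trunk, batch)
  hd <- dense_forward(model$head, tf$emb)
  list(logits = hd$out, trunk_caches = tf$caches, head_cache = hd$cache)
}

#' @exportS3Method
nn_backward.cnn_model <- function(model, fw, gz) {
  hb <- dense_backward(model$head, fw$head_cache, gz)
  tg <- cnn_trunk_backward(model$trunk, fw$trunk_caches, hb$gx)
  list(trunk = tg, head = hb$grads)
}

#' @exportS3Method
nn_trainable.cnn_model <- function(model)
  list(trunk = lapply(model$trunk, layer_trainable),
       head = layer_trainable(model$head))

#' @exportS3Method
nn_set_trainable.cnn_model <- function(model, tr) {
  for (i in seq_along(model$trunk))
    model$trunk[[i]] <- layer_set_trainable(model$trunk[[i]], tr$trunk[[i]])
  model$head <- layer_set_trainable(model$head, tr$head)
  model
}

#' @exportS3Method
nn_trainable.rnn_model <- nn_trainable.cnn_model
#' @exportS3Method
nn_set_trainable.rnn_model <- nn_set_trainable.cnn_model

#' @exportS3Method
nn_forward.rnn_model <- function(model, batch) {
  tf <- rnn_trunk_forward(model$trunk, batch)
  hd <- dense_forward(model$head, tf$emb)
  list(logits = hd$out, trunk_caches = tf$caches, head_cache = hd$cache)
}

#' @exportS3Method
nn_backward.rnn_model <- function(model, fw, gz) {
  hb <- dense_backward(model$head, fw$head_cache, gz)
  tg <- rnn_trunk_backward(model$trunk, fw$trunk_caches, hb$gx)
  list(trunk = tg, head = hb$grads)
}

# ---- shared minibatch training loop ----------------------------------

net_train_loop <- function(model, batch_fn, n, y, cfg) {
  Y <- rbind(1 - y, y)                    # one-hot: row 1 normal, row 2 arousal
  hist_train <- numeric(0); hist_val <- numeric(0)
  with_seed(cfg$seed + 1L, {
    n_val <- max(1L, round(cfg$val_fraction * n))
    val_idx <- sort(sample.int(n, n_val))
    tr_idx <- setdiff(seq_len(n), val_idx)
    flat0 <- flat_leaves(nn_trainable(model))
    adam_m <- lapply(flat0, function(p) p * 0)
    adam_v <- adam_m
    tstep <- 0L
    best_val <- Inf; best_tr <- NULL; bad <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        bidx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        fw <- nn_forward(model, batch_fn(bidx))
        sc <- softmax_ce(fw$logits, Y[, bidx, drop = FALSE])
        if (!is.finite(sc$loss))
          stop("non-finite training loss at epoch ", ep,
               " (batch starting ", b0, "); try a smaller learning rate")
        grads <- nn_backward(model, fw, sc$grad)
        gflat <- flat_leaves(grads, prefix = "p")
        tr <- nn_trainable(model)
        pflat <- flat_leaves(tr)
        tstep <- tstep + 1L
        for (nm in names(pflat)) {
          g <- gflat[[nm]]
          if (is.null(g)) next
          up <- adam_update_param(pflat[[nm]], g, adam_m[[nm]],
                                  adam_v[[nm]], cfg$lr, tstep)
          pflat[[nm]] <- up$p
          adam_m[[nm]] <- up$m
          adam_v[[nm]] <- up$v
        }
        model <- nn_set_trainable(model, unflatten_into(tr, pflat))
        ep_loss <- ep_loss + sc$loss * length(bidx)
        ep_n <- ep_n + length(bidx)
      }
      # validation loss
      vl <- 0
      for (b0 in seq(1L, length(val_idx), by = cfg$batch_size)) {
        bidx <- val_idx[b0:min(b0 + cfg$batch_size - 1L, length(val_idx))]
        fw <- nn_forward(model, batch_fn(bidx))
        vl <- vl + softmax_ce(fw$logits, Y[, bidx, drop = FALSE])$loss *
          length(bidx)
      }
      vl <- vl / length(val_idx)
      hist_train <- c(hist_train, ep_loss / ep_n)
      hist_val <- c(hist_val, vl)
      if (cfg$verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        ep_loss / ep_n, vl))
      if (vl < best_val - 1e-6) {
        best_val <- vl
        best_tr <- nn_trainable(model)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
    if (!is.null(best_tr)) model <- nn_set_trainable(model, best_tr)
    model$trained <- TRUE
    model$history <- list(train = hist_train, val = hist_val,
                          best_val = best_val)
    model
  })
}

# ---- training / prediction generics ----------------------------------

#' Train a base classifier
#'
#' Dispatches on the model class.  Network models (`cnn_model`,
#' `rnn_model`, `premerge_model`) are trained with seeded minibatch Adam
#' on softmax cross-entropy, keeping the weights of the best
#' validation-loss epoch; the random forest is fitted in one call.
#'
#' @param model a built, untrained model.
#' @param x model-appropriate input: `6000 x n` waveform matrix for the
#'   CNN, `29 x 8 x n` band-matrix array for the RNN,
#'   `list(wave =, band =)` for the pre-merge network, `n x 42` expert
#'   matrix for the forest.
#' @param y 0/1 segment labels of length n.
#' @param config a [train_config()].
#' @return the trained model (with `history` for the networks).
#' @export
train_submodel <- function(model, x, y, config = train_config()) {
  UseMethod("train_submodel")
}

#' @export
train_submodel.cnn_model <- function(model, x, y, config = train_config()) {
  stopifnot(nrow(x) == model$spec$input_length)
  y <- as.numeric(as.logical(y))
  Xstd <- standardize_waveform(x)
  net_train_loop(model, function(idx) cnn_batch(Xstd, idx),
                 length(y), y, config)
}

#' @export
train_submodel.rnn_model <- function(model, x, y, config = train_config()) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == model$spec$n_steps,
            dim(x)[2] == model$spec$n_features)
  y <- as.numeric(as.logical(y))
  model$norm <- fit_band_norm(x)
  An <- apply_band_norm(x, model$norm)
  net_train_loop(model, function(idx) rnn_batch(An, idx),
                 length(y), y, config)
}

#' Class-probability predictions of a trained base classifier
#'
#' @param model a trained model.
#' @param x input in the same form as for [train_submodel()].
#' @param batch_size forward-pass batch size for the networks.
#' @return `n x 2` matrix with columns `normal`, `arousal`, each row
#'   summing to 1.
#' @export
predict_proba <- function(model, x, batch_size = 256L) {
  UseMethod("predict_proba")
}

net_predict <- function(model, batch_fn, n, batch_size) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("normal", "arousal")))
  for (b0 in seq(1L, n, by = batch_size)) {
    bidx <- b0:min(b0 + batch_size - 1L, n)
    fw <- nn_forward(model, batch_fn(bidx))
    out[bidx, ] <- t(softmax_probs(fw$logits))
  }
  out
}

#' @export
predict_proba.cnn_model <- function(model, x, batch_size = 256L) {
  Xstd <- standardize_waveform(x)
  net_predict(model, function(idx) cnn_batch(Xstd, idx), ncol(x), batch_size)
}

#' @export
predict_proba.rnn_model <- function(model, x, batch_size = 256L) {
  if (is.null(model$norm)) stop("model has not been trained")
  An <- apply_band_norm(x, model$norm)
  net_predict(model, function(idx) rnn_batch(An, idx), dim(x)[3], batch_size)
}
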