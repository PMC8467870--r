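#' Specification of the waveform 1D CNN
#'
#' Four convolution blocks on the raw 6000-sample segment, each block two
#' valid (no-padding) ReLU convolutions followed by a length-2 max-pool;
#' kernel lengths 50, 30, 10 and 2 with channel widths 20/20, 20/24,
#' 12/12 and 12/12; then global average pooling to a 12-vector and a
#' softmax dense output of 2.
#'
#' @param input_length segment length in samples (default 6000).
#' @return list of class `cnn_spec` with a `blocks` table
#'   (kernel, c_in, c_out per convolution).
#' @export
cnn_spec <- function(input_length = 6000L) {
  blocks <- data.frame(
    name = paste0("Conv1D", 1:8),
    kernel = c(50L, 50L, 30L, 30L, 10L, 10L, 2L, 2L),
    c_in  = c(1L, 20L, 20L, 20L, 24L, 12L, 12L, 12L),
    c_out = c(20L, 20L, 20L, 24L, 12L, 12L, 12L, 12L),
    pool_after = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  structure(list(input_length = as.integer(input_length), blocks = blocks,
                 embedding_dim = 12L, n_classes = 2L),
            class = "cnn_spec")
}

#' Build the waveform CNN with its parameter census
#'
#' Constructs the network, counts trainable parameters per layer and
#' traces the output shape through every layer.
#'
#' @param spec a [cnn_spec()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `cnn_model` with fields `trunk` (layers up
#'   to the 12-dimensional global-average-pooling embedding), `head` (the
#'   softmax dense layer) and `census` (data.frame: layer, n_params,
#'   out_x, out_y).
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  bl <- spec$blocks
  census <- data.frame(layer = "Input", n_params = 0L,
                       out_x = spec$input_length, out_y = 1L)
  len <- spec$input_length
  trunk <- list()
  with_seed(seed, {
    pool_i <- 0L
    for (i in seq_len(nrow(bl))) {
      if (len - bl$kernel[i] + 1L < 1L)
        stop("layer ", bl$name[i], ": input length ", len,
             " shorter than kernel ", bl$kernel[i])
      trunk[[length(trunk) + 1L]] <-
        nn_conv_layer(bl$kernel[i], bl$c_in[i], bl$c_out[i])
      len <- len - bl$kernel[i] + 1L
      census <- rbind(census, data.frame(
        layer = bl$name[i],
        n_params = bl$kernel[i] * bl$c_in[i] * bl$c_out[i] + bl$c_out[i],
        out_x = len, out_y = bl$c_out[i]))
      if (bl$pool_after[i]) {
        pool_i <- pool_i + 1L
        trunk[[length(trunk) + 1L]] <- nn_pool_layer()
        len <- len %/% 2L
        census <- rbind(census, data.frame(
          layer = paste0("Maxpooling", pool_i), n_params = 0L,
          out_x = len, out_y = bl$c_out[i]))
      }
      if (i < nrow(bl) && bl$c_out[i] != bl$c_in[i + 1L])
        stop("channel mismatch between ", bl$name[i], " and ",
             bl$name[i + 1L])
    }
    trunk[[length(trunk) + 1L]] <- nn_gap_layer()
    census <- rbind(census, data.frame(
      layer = "Global Average Pooling", n_params = 0L,
      out_x = spec$embedding_dim, out_y = 1L))
    head_layer <- nn_dense_layer(spec$embedding_dim, spec$n_classes)
    census <- rbind(census, data.frame(
      layer = "Dense (output)",
      n_params = spec$embedding_dim * spec$n_classes + spec$n_classes,
      out_x = spec$n_classes, out_y = 1L))
    structure(list(spec = spec, trunk = trunk, head = head_layer,
                   census = census, seed = as.integer(seed),
                   trained = FALSE),
              class = c("cnn_model", "nn_model"))
  })
}

# forward through the conv trunk; x: (L, 1, B) -> embedding (12, B)
cnn_trunk_forward <- function(trunk, x) {
  caches <- vector("list", length(trunk))
  for (i in seq_along(trunk)) {
    ly <- trunk[[i]]
    r <- switch(ly$type,
                conv = conv_forward(ly, x),
                pool = pool_forward(ly, x),
                gap = gap_forward(ly, x))
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(emb = x, caches = caches)
}

cnn_trunk_backward <- function(trunk, caches, g) {
  grads <- vector("list", length(trunk))
  for (i in rev(seq_along(trunk))) {
    ly <- trunk[[i]]
    r <- switch(ly$type,
                conv = conv_backward(ly, caches[[i]], g),
                pool = pool_backward(ly, caches[[i]], g),
                gap = gap_backward(ly, caches[[i]], g))
    g <- r$gx
    grads[i] <- list(r$grads)   # keep NULL placeholders for pool/gap
  }
  grads
}

# per-segment z-scoring of a (L x n) waveform matrix
standardize_waveform <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

cnn_batch <- function(Xstd, idx) {
  array(Xstd[, idx], c(nrow(Xstd), 1L, length(idx)))
}
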