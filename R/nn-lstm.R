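# LSTM layers for the band-power sequence model.  Sequences are arrays
# (B, features, T); hidden states are (B, H) matrices.  Gate weight
# columns are blocked [input | forget | cell | output]; the forget-gate
# bias starts at 1.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_lstm_layer <- function(d_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(type = "lstm", d_in = d_in, h = h,
       W = glorot(d_in, 4 * h), U = glorot(h, 4 * h), b = b)
}

lstm_forward <- function(ly, X, reverse = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[3]; H <- ly$h
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- if (reverse) Tn:1 else 1:Tn
  seq_out <- array(0, c(B, H, Tn))
  caches <- vector("list", Tn)
  for (t in steps) {
    xt <- matrix(X[, , t], B, ly$d_in)
    z <- xt %*% ly$W + h %*% ly$U
    z <- sweep(z, 2, ly$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    caches[[t]] <- list(x = xt, h_prev = h, c_prev = cc,
                        i = i, f = f, g = g, o = o, tc = tc)
    cc <- c_new
    h <- o * tc
    seq_out[, , t] <- h
  }
  list(seq = seq_out, last = h,
       cache = list(steps = steps, caches = caches, B = B, Tn = Tn))
}

# gseq: (B, H, T) gradients on every step's output (zeros allowed);
# returns gx (B, d_in, T) and parameter gradients
lstm_backward <- function(ly, cache, gseq) {
  B <- cache$B; Tn <- cache$Tn; H <- ly$h
  gW <- ly$W * 0; gU <- ly$U * 0; gb <- ly$b * 0
  gx <- array(0, c(B, ly$d_in, Tn))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(cache$steps)) {
    cs <- cache$caches[[t]]
    dh_t <- dh + matrix(gseq[, , t], B, H)
    do <- dh_t * cs$tc
    dc <- dc + dh_t * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dc <- dc * cs$f
    dz <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                dg * (1 - cs$g^2),
                do * cs$o * (1 - cs$o))
    gW <- gW + crossprod(cs$x, dz)
    gU <- gU + crossprod(cs$h_prev, dz)
    gb <- gb + colSums(dz)
    dh <- dz %*% t(ly$U)
    gx[, , t] <- dz %*% t(ly$W)
  }
  list(gx = gx, grads = list(W = gW, U = gU, b = gb))
}

nn_bilstm_layer <- function(d_in, h) {
  list(type = "bilstm", d_in = d_in, h = h,
       fwd = nn_lstm_layer(d_in, h), bwd = nn_lstm_layer(d_in, h))
}

bilstm_forward <- function(ly, X) {
  rf <- lstm_forward(ly$fwd, X, reverse = FALSE)
  rb <- lstm_forward(ly$bwd, X, reverse = TRUE)
  B <- dim(X)[1]; Tn <- dim(X)[3]; H <- ly$h
  seq_out <- array(0, c(B, 2 * H, Tn))
  seq_out[, 1:H, ] <- rf$seq
  seq_out[, (H + 1):(2 * H), ] <- rb$seq
  list(seq = seq_out, cache = list(fwd = rf$cache, bwd = rb$cache, H = H))
}

bilstm_backward <- function(ly, cache, gseq) {
  H <- cache$H
  bf <- lstm_backward(ly$fwd, cache$fwd, gseq[, 1:H, , drop = FALSE])
  bb <- lstm_backward(ly$bwd, cache$bwd,
                      gseq[, (H + 1):(2 * H), , drop = FALSE])
  list(gx = bf$gx + bb$gx,
       grads = list(fwd = bf$grads, bwd = bb$grads))
}
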