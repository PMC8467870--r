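#' Low-pass filter specification
#'
#' The defaults describe the powerline-removal filter used throughout:
#' order 127 with passband and stopband edges at 40 and 42 Hz.  The
#' default realization is a linear-phase FIR least-squares design of the
#' stated order; `"iir"` selects a conventional low-order Butterworth
#' applied forward-backward instead (a 127th-order IIR filter would be
#' numerically pathological, so the FIR realization is the one that honors
#' the printed order and edges).
#'
#' @param order filter order (FIR taps = order + 1).
#' @param passband_edge passband edge in Hz.
#' @param stopband_edge stopband edge in Hz.
#' @param realization `"fir"` (default) or `"iir"`.
#' @param iir_order Butterworth order used when `realization = "iir"`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 127L, passband_edge = 40,
                        stopband_edge = 42, realization = c("fir", "iir"),
                        iir_order = 8L) {
  realization <- match.arg(realization)
  if (passband_edge >= stopband_edge)
    stop("passband edge must be below the stopband edge")
  structure(list(order = as.integer(order), passband_edge = passband_edge,
                 stopband_edge = stopband_edge, realization = realization,
                 iir_order = as.integer(iir_order)),
            class = "filter_spec")
}

# linear-phase least-squares FIR low-pass, even length (type II).
# Desired response: 1 on [0, fp], 0 on [fs, Nyquist], transition
# unconstrained.  Closed-form band integrals give the normal equations.
fir_ls_lowpass <- function(n_taps, fp, fs_edge, fs) {
  if (n_taps %% 2 != 0) stop("even tap count expected (odd order)")
  M <- n_taps / 2
  Fp <- fp / fs; Fs <- fs_edge / fs; Fn <- 0.5
  tau <- seq_len(M) - 0.5  # cos(2*pi*F*tau_k) basis
  cint <- function(tt, u, v) {
    # integral of cos(2*pi*F*tt) dF over [u, v]
    ifelse(abs(tt) < 1e-12, v - u,
           (sin(2 * pi * v * tt) - sin(2 * pi * u * tt)) / (2 * pi * tt))
  }
  G <- matrix(0, M, M)
  for (k in seq_len(M)) {
    td <- tau[k] - tau
    ts <- tau[k] + tau
    G[k, ] <- 0.5 * (cint(td, 0, Fp) + cint(ts, 0, Fp) +
                     cint(td, Fs, Fn) + cint(ts, Fs, Fn))
  }
  d <- cint(tau, 0, Fp)
  b_half <- solve(G, d)
  h_half <- rev(b_half) / 2  # h[0..M-1]
  c(h_half, rev(h_half))
}

#' Design the powerline-removal low-pass filter
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz (default 200).
#' @return An `eeg_filter`: list with numerator `b`, denominator `a`
#'   (1 for FIR), `group_delay` (samples, FIR only), `fs` and the spec.
#' @export
design_filter <- function(spec = filter_spec(), fs = 200) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$stopband_edge >= fs / 2)
    stop("stopband edge must be below the Nyquist frequency")
  if (spec$realization == "fir") {
    b <- fir_ls_lowpass(spec$order + 1L, spec$passband_edge,
                        spec$stopband_edge, fs)
    filt <- list(b = b, a = 1, group_delay = spec$order / 2,
                 fs = fs, spec = spec)
  } else {
    wc <- (spec$passband_edge + spec$stopband_edge) / fs  # of Nyquist
    bt <- signal::butter(spec$iir_order, wc, type = "low")
    filt <- list(b = bt$b, a = bt$a, group_delay = NA_real_,
                 fs = fs, spec = spec)
  }
  structure(filt, class = "eeg_filter")
}

#' Complex frequency response of a designed filter
#'
#' @param filt an `eeg_filter`.
#' @param freqs frequencies in Hz.
#' @return complex vector `H(f)`.
#' @export
filter_response <- function(filt, freqs) {
  w <- 2 * pi * freqs / filt$fs
  zb <- vapply(w, function(wi)
    sum(filt$b * exp(-1i * wi * (seq_along(filt$b) - 1))), complex(1))
  if (length(filt$a) == 1 && filt$a[1] == 1) return(zb)
  za <- vapply(w, function(wi)
    sum(filt$a * exp(-1i * wi * (seq_along(filt$a) - 1))), complex(1))
  zb / za
}

# FFT linear convolution of x with kernel b
fft_conv <- function(x, b) {
  n <- length(x) + length(b) - 1L
  nfft <- stats::nextn(n, 2)
  Re(fft(fft(c(x, numeric(nfft - length(x)))) *
           fft(c(b, numeric(nfft - length(b)))), inverse = TRUE))[1:n] / nfft
}

#' Apply the low-pass filter to a record
#'
#' FIR filtering is linear-phase; the output is shifted back by the
#' (rounded) group delay with edge-replicated padding so the per-sample
#' arousal labels stay aligned with the filtered signal, and has the same
#' length as the input.  The IIR realization uses forward-backward
#' filtering (zero phase by construction).
#'
#' @param record an `eeg_record` (or plain numeric vector).
#' @param filt an `eeg_filter` from [design_filter()].
#' @return filtered record of the same class and length; labels unchanged.
#' @export
apply_filter <- function(record, filt) {
  stopifnot(inherits(filt, "eeg_filter"))
  x <- if (inherits(record, "eeg_record")) record$samples else record
  n <- length(x)
  if (n == 0) stop("empty record")
  if (filt$spec$realization == "fir") {
    delay <- as.integer(round(filt$group_delay + 0.5))  # 63.5 -> 64
    xp <- c(rep(x[1], delay), x, rep(x[n], delay))
    z <- fft_conv(xp, filt$b)
    y <- z[(2 * delay) + seq_len(n)]
  } else {
    y <- as.numeric(signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), x))
  }
  if (inherits(record, "eeg_record")) {
    record$samples <- y
    record
  } else y
}

#' Segment label from per-sample arousal labels
#'
#' A segment is positive iff it contains a contiguous run of arousal
#' samples lasting at least `min_duration` seconds (3 s by default, the
#' minimum arousal duration in the AASM scoring rules).  Runs truncated
#' by the segment boundary count only their in-window portion.
#'
#' @param labels 0/1 vector of per-sample labels for one segment.
#' @param min_duration minimum contiguous arousal duration in seconds.
#' @param fs sampling rate in Hz.
#' @param expected_length segment length check (NULL to skip).
#' @return 0 or 1.
#' @export
label_segment <- function(labels, min_duration = 3, fs = 200,
                          expected_length = 6000L) {
  if (!is.null(expected_length) && length(labels) != expected_length)
    stop("expected ", expected_length, " per-sample labels, got ",
         length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  r <- rle(labels)
  runs <- r$lengths[r$values == 1L]
  as.integer(length(runs) > 0 && max(runs) >= min_duration * fs)
}

#' Split a record into labeled 30-second segments
#'
#' Discards the first and last `discard_edges` seconds (one hour by
#' default), then cuts the remainder into consecutive non-overlapping
#' windows of `window` seconds; a trailing partial window is dropped.
#' Each segment carries its per-sample labels and the segment-level label
#' from [label_segment()].
#'
#' @param record an `eeg_record`.
#' @param discard_edges seconds discarded at each end (default 3600).
#' @param window window length in seconds (default 30).
#' @param min_duration passed to [label_segment()].
#' @return list of `eeg_segment` objects (fields `samples`,
#'   `sample_labels`, `label`, `record_id`, `start_offset` in seconds).
#'   Short records yield an empty list.
#' @export
segment_record <- function(record, discard_edges = 3600, window = 30,
                           min_duration = 3) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  n <- length(record$samples)
  skip <- round(discard_edges * fs)
  usable <- n - 2 * skip
  win <- round(window * fs)
  n_seg <- if (usable >= win) usable %/% win else 0L
  out <- vector("list", n_seg)
  for (m in seq_len(n_seg)) {
    i0 <- skip + (m - 1L) * win
    idx <- (i0 + 1L):(i0 + win)
    sl <- record$labels[idx]
    out[[m]] <- structure(list(
      samples = record$samples[idx],
      sample_labels = sl,
      label = label_segment(sl, min_duration, fs, expected_length = win),
      record_id = record$id,
      start_offset = i0 / fs), class = "eeg_segment")
  }
  out
}

#' Segment manifest as a data.frame
#'
#' @param segments list of `eeg_segment`s.
#' @return data.frame with `record_id`, `start_offset`, `label`.
#' @export
segment_manifest <- function(segments) {
  data.frame(
    record_id = vapply(segments, function(s) s$record_id, character(1)),
    start_offset = vapply(segments, function(s) s$start_offset, numeric(1)),
    label = vapply(segments, function(s) s$label, integer(1))
  )
}
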