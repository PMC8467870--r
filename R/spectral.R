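#' Frequency bands and their 1-based PSD bin ranges
#'
#' Bin spacing is 0.5 Hz (window length 400 at 200 Hz); bin 1 is DC.
#' Delta 0-4 Hz (bins 1-9), theta 4-8 Hz (10-17), alpha 8-12 Hz (18-25),
#' beta 14-30 Hz (30-61) and the full band 0-40 Hz (1-81).
#'
#' @return data.frame with columns `band`, `lo_bin`, `hi_bin`.
#' @export
band_bins <- function() {
  data.frame(
    band   = c("delta", "theta", "alpha", "beta", "full"),
    lo_bin = c(1L, 10L, 18L, 30L, 1L),
    hi_bin = c(9L, 17L, 25L, 61L, 81L),
    stringsAsFactors = FALSE
  )
}

#' Column names of the band-power feature matrix
#' @return character vector of length 8.
#' @export
band_feature_names <- function() {
  c("delta", "theta", "alpha", "beta", "full",
    "delta_theta", "theta_alpha", "delta_alpha")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the `n_tapers` most spectrally concentrated sequences of
#' length `n` for half-bandwidth `nw / n`, via the classical symmetric
#' tridiagonal formulation, unit-energy normalized.  The default
#' time-bandwidth product `nw = 4.5` yields 2*nw - 1 = 8 well-concentrated
#' tapers, matching the taper count used throughout the package.
#'
#' @param n taper length in samples (default 400).
#' @param n_tapers number of tapers (default 8).
#' @param nw time-bandwidth product (default 4.5).
#' @return An object of class `taper_bank`: list with `h` (n x n_tapers
#'   matrix of taper coefficients), `eigenvalues` (spectral
#'   concentrations), `n`, `n_tapers`, `nw`.
#' @export
compute_dpss <- function(n = 400L, n_tapers = 8L, nw = 4.5) {
  if (n_tapers >= n) stop("n_tapers must be smaller than the taper length")
  W <- nw / n
  idx <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * idx) / 2)^2 * cos(2 * pi * W)
  off_v <- idx[-1] * (n - idx[-1]) / 2
  Tm <- matrix(0, n, n)
  Tm[cbind(seq_len(n), seq_len(n))] <- diag_v
  Tm[cbind(seq_len(n - 1), 2:n)] <- off_v
  Tm[cbind(2:n, seq_len(n - 1))] <- off_v
  eg <- eigen(Tm, symmetric = TRUE)
  h <- eg$vectors[, seq_len(n_tapers), drop = FALSE]
  # unit energy and a deterministic sign convention: symmetric tapers have
  # positive mean, antisymmetric tapers rise from the left
  for (i in seq_len(n_tapers)) {
    h[, i] <- h[, i] / sqrt(sum(h[, i]^2))
    s <- sum(h[, i])
    if (abs(s) < 1e-7) s <- sum(h[, i] * (n - 1 - 2 * idx))
    if (s < 0) h[, i] <- -h[, i]
  }
  # spectral concentration via the sinc kernel quadratic form
  dmn <- outer(idx, idx, "-")
  A <- sin(2 * pi * W * dmn) / (pi * dmn)
  diag(A) <- 2 * W
  lambda <- vapply(seq_len(n_tapers),
                   function(i) drop(crossprod(h[, i], A %*% h[, i])),
                   numeric(1))
  if (any(lambda < 0.9))
    warning("some tapers are poorly concentrated (eigenvalue < 0.9); ",
            "consider fewer tapers or a larger time-bandwidth product")
  structure(list(h = h, eigenvalues = lambda, n = n,
                 n_tapers = n_tapers, nw = nw),
            class = "taper_bank")
}

#' Split a 30-s segment into 2-s frames with 50% overlap
#'
#' A 6000-sample segment yields 29 frames of 400 samples hopping by 200.
#'
#' @param x numeric vector of 6000 samples (or any length that is
#'   `frame + k * hop`).
#' @param frame frame length in samples (default 400).
#' @param hop hop size in samples (default 200).
#' @return `frame x n_frames` matrix, one frame per column.
#' @export
frame_segment <- function(x, frame = 400L, hop = 200L) {
  n <- length(x)
  if (n < frame || (n - frame) %% hop != 0)
    stop("segment length ", n, " is not frame + k * hop")
  n_frames <- (n - frame) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  vapply(starts, function(s) x[(s + 1L):(s + frame)], numeric(frame))
}

#' Multitaper power spectral density of one frame
#'
#' Averages the squared DFT magnitudes of the tapered frame over all
#' tapers (unweighted), then folds to a one-sided spectrum: interior bins
#' are doubled, DC and the window Nyquist bin are not.  With unit-energy
#' tapers the sum over the 201 one-sided bins estimates the frame
#' variance (power), making Parseval checks exact in expectation.  No
#' demeaning is applied, so the DC bin carries the frame mean.
#'
#' @param frame numeric vector whose length equals the taper length.
#' @param tapers a `taper_bank` from [compute_dpss()].
#' @return numeric vector of `n/2 + 1` nonnegative PSD values
#'   (power per bin), 0.5 Hz apart for the default 400/200 Hz setup.
#' @export
multitaper_psd <- function(frame, tapers) {
  stopifnot(inherits(tapers, "taper_bank"))
  n <- tapers$n
  if (length(frame) != n)
    stop("frame length ", length(frame), " != taper length ", n)
  X <- stats::mvfft(tapers$h * frame)
  half <- n %/% 2 + 1L
  P <- rowMeans(Mod(X[seq_len(half), , drop = FALSE])^2) / n
  scale <- rep(2, half)
  scale[1L] <- 1
  if (n %% 2 == 0) scale[half] <- 1
  P * scale
}

# Composite Simpson integration over uniformly spaced values; when the
# interval count is odd the last three intervals use the 3/8 rule.
simpson_integral <- function(values, h) {
  npts <- length(values)
  m <- npts - 1L
  if (m < 1L) stop("need at least two points to integrate")
  if (m == 1L) return(h * sum(values) / 2)  # trapezoid fallback
  if (m == 2L)
    return(h / 3 * (values[1] + 4 * values[2] + values[3]))
  if (m %% 2 == 0) {
    w <- c(1, rep(c(4, 2), length.out = m - 1), 1)
    return(h / 3 * sum(w * values))
  }
  # odd interval count: Simpson on the first m-3 intervals, 3/8 on the
  # last three (m == 3 is a pure 3/8 rule)
  head_val <- if (m > 3L) simpson_integral(values[1:(m - 2L)], h) else 0
  tail_val <- 3 * h / 8 * (values[npts - 3L] + 3 * values[npts - 2L] +
                             3 * values[npts - 1L] + values[npts])
  head_val + tail_val
}

#' Band power by numerical integration of the PSD
#'
#' Integrates the one-sided PSD over the band's bins (Table of
#' [band_bins()]) with the composite Simpson rule (3/8-corrected when the
#' bin count leaves an odd number of intervals), treating the PSD as a
#' density over frequency with 0.5 Hz spacing.
#'
#' @param psd numeric vector of 201 one-sided PSD values.
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"full"`.
#' @param df bin spacing in Hz (default 0.5).
#' @return nonnegative band power.
#' @export
band_power <- function(psd, band, df = 0.5) {
  bb <- band_bins()
  row <- bb[bb$band == band, ]
  if (nrow(row) != 1L) stop("unknown band: ", band)
  if (length(psd) < row$hi_bin) stop("PSD has too few bins for ", band)
  simpson_integral(psd[row$lo_bin:row$hi_bin], df)
}

# ratio with the package-wide convention: 0/0 -> 0, x/0 -> cap
power_ratio <- function(num, den, cap = 1e6) {
  out <- ifelse(den > 0, num / den, ifelse(num > 0, cap, 0))
  pmin(out, cap)
}

#' The 29 x 8 band-power feature matrix of one segment
#'
#' Rows are the 29 overlapping 2-s frames; columns are the five band
#' powers (delta, theta, alpha, beta, full) followed by the ratios
#' delta/theta, theta/alpha and delta/alpha.
#'
#' @param x numeric vector, one 6000-sample segment (an `eeg_segment`'s
#'   samples are accepted too).
#' @param tapers a `taper_bank`; defaults to the package's 400-sample,
#'   8-taper bank (cached).
#' @param ratio_cap ceiling for ratios with a zero denominator.
#' @return numeric matrix `29 x 8` with [band_feature_names()] columns.
#' @export
band_matrix <- function(x, tapers = default_tapers(), ratio_cap = 1e6) {
  if (inherits(x, "eeg_segment")) x <- x$samples
  frames <- frame_segment(x, frame = tapers$n)
  psd <- apply(frames, 2, multitaper_psd, tapers = tapers)
  bands <- c("delta", "theta", "alpha", "beta", "full")
  pw <- vapply(bands, function(b) apply(psd, 2, band_power, band = b),
               numeric(ncol(frames)))
  out <- cbind(pw,
               power_ratio(pw[, "delta"], pw[, "theta"], ratio_cap),
               power_ratio(pw[, "theta"], pw[, "alpha"], ratio_cap),
               power_ratio(pw[, "delta"], pw[, "alpha"], ratio_cap))
  colnames(out) <- band_feature_names()
  out
}

.taper_cache <- new.env(parent = emptyenv())

#' Package-default taper bank (400 samples, 8 tapers, NW = 4.5), cached
#' @return a `taper_bank`.
#' @export
default_tapers <- function() {
  if (is.null(.taper_cache$bank))
    .taper_cache$bank <- compute_dpss(400L, 8L, 4.5)
  .taper_cache$bank
}
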