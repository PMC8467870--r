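#' Hjorth parameters of a signal
#'
#' Activity is the sample variance (N-1 denominator); mobility is
#' `sqrt(activity(diff(x)) / activity(x))`, a proxy for the dominant
#' frequency; complexity is `mobility(diff(x)) / mobility(x)`, a
#' bandwidth proxy.  `diff` is the first difference, shortening the
#' signal by one sample per application.
#'
#' @param x numeric vector of length >= 3.
#' @return list with `activity`, `mobility`, `complexity`.  A constant
#'   signal has zero activity; mobility and complexity are then undefined
#'   and returned as 0 with a warning.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  a0 <- var(x)
  if (a0 == 0) {
    warning("constant signal: mobility and complexity undefined, returning 0")
    return(list(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  m0 <- sqrt(var(d1) / a0)
  m1 <- sqrt(var(d2) / var(d1))
  list(activity = a0, mobility = m0,
       complexity = if (m0 > 0) m1 / m0 else 0)
}

# shared standardized central moment with the package convention:
# 1/N moment over an (N-1)-denominator standard deviation
std_moment <- function(x, order, textbook = FALSE) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  mu <- mean(x)
  s <- if (textbook) sqrt(mean((x - mu)^2)) else sd(x)
  if (s == 0) {
    warning("zero standard deviation: returning 0")
    return(0)
  }
  mean((x - mu)^order) / s^order
}

#' Kurtosis (fourth standardized moment)
#'
#' Uses a 1/N fourth moment over the (N-1)-denominator standard
#' deviation.  This hybrid convention still tends to 3 for Gaussian data
#' as N grows; `textbook = TRUE` switches to the plain 1/N moment
#' estimator throughout.
#'
#' @param x numeric vector.
#' @param textbook use the all-1/N convention instead.
#' @return kurtosis value (3 for a large Gaussian sample).
#' @export
sample_kurtosis <- function(x, textbook = FALSE) {
  std_moment(x, 4, textbook)
}

#' Skewness (third standardized moment)
#'
#' Same convention as [sample_kurtosis()]: 1/N third moment over the
#' (N-1)-denominator standard deviation cubed.
#'
#' @inheritParams sample_kurtosis
#' @return skewness value (0 for a symmetric sample).
#' @export
sample_skewness <- function(x, textbook = FALSE) {
  std_moment(x, 3, textbook)
}

#' Averaged numerical gradient
#'
#' Mean of the central-difference gradient (one-sided differences at the
#' ends); for a linear ramp this recovers the slope per sample exactly.
#'
#' @param x numeric vector of length >= 2.
#' @return scalar mean gradient.
#' @export
mean_gradient <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  mean(g)
}

#' Names of the 42 expert-defined features, in storage order
#'
#' Six time-domain features (mean gradient, kurtosis, the three Hjorth
#' parameters, skewness) followed by 36 frequency-domain features: the
#' minimum, mean, standard deviation and 95th percentile of each of the 8
#' band-matrix columns, then the kurtosis of the four sub-band columns.
#'
#' @return character vector of length 42.
#' @export
expert_feature_names <- function() {
  bands <- band_feature_names()
  c("grad_mean", "kurtosis", "hjorth_activity", "hjorth_mobility",
    "hjorth_complexity", "skewness",
    paste0("min_", bands), paste0("mean_", bands),
    paste0("sd_", bands), paste0("p95_", bands),
    paste0("kurt_", bands[1:4]))
}

#' Assemble the 1 x 42 expert-defined feature vector of a segment
#'
#' @param x numeric vector of segment samples (or an `eeg_segment`).
#' @param bm the segment's 29 x 8 band-power matrix from [band_matrix()];
#'   computed on the fly when omitted.
#' @return named numeric vector of length 42 in [expert_feature_names()]
#'   order.  The 95th percentile interpolates linearly between order
#'   statistics.
#' @export
expert_vector <- function(x, bm = NULL) {
  if (inherits(x, "eeg_segment")) x <- x$samples
  if (is.null(bm)) bm <- band_matrix(x)
  if (!is.matrix(bm) || ncol(bm) != 8)
    stop("band matrix must have 8 columns")
  hj <- hjorth(x)
  time_part <- c(mean_gradient(x), sample_kurtosis(x), hj$activity,
                 hj$mobility, hj$complexity, sample_skewness(x))
  mins <- apply(bm, 2, min)
  means <- colMeans(bm)
  sds <- apply(bm, 2, sd)
  p95 <- apply(bm, 2, quantile, probs = 0.95, names = FALSE, type = 7)
  kurts <- apply(bm[, 1:4, drop = FALSE], 2, sample_kurtosis)
  out <- c(time_part, mins, means, sds, p95, kurts)
  names(out) <- expert_feature_names()
  out
}
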