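#' Construct a single-channel EEG record
#'
#' @param samples numeric amplitude series (arbitrary units).
#' @param labels per-sample 0/1 arousal labels; defaults to all zero.
#' @param sampling_rate sampling rate in Hz (default 200).
#' @param id record identifier.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, labels = NULL, sampling_rate = 200,
                       id = "record") {
  if (is.null(labels)) labels <- integer(length(samples))
  labels <- as.integer(labels)
  if (length(labels) != length(samples))
    stop("labels and samples must have equal length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(list(samples = as.numeric(samples), labels = labels,
                 sampling_rate = sampling_rate, id = id),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s': %d samples @ %g Hz (%.1f min), %.1f%% arousal>\n",
              x$id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate / 60,
              100 * mean(x$labels)))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$samples)
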