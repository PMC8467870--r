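# Minimal WFDB (PhysioNet waveform-database) dialect: a text .hea header
# plus a 16-bit little-endian interleaved .dat signal file (format 16),
# the layout used by the CinC 2018 polysomnography records.  Physical
# units are recovered as (adc - baseline) / gain.

#' Write signals as a WFDB record (format 16)
#'
#' @param signals numeric vector or `n x nsig` matrix of physical values.
#' @param fs sampling rate in Hz.
#' @param dir output directory.
#' @param name record name (basename of the .hea/.dat pair).
#' @param channels channel names; default `C3-M2` for a single channel.
#' @param labels optional per-sample 0/1 arousal labels, written to
#'   `<name>.arousal` as a plain text vector.
#' @return path to the written .hea file, invisibly.
#' @export
write_wfdb <- function(signals, fs, dir, name, channels = NULL,
                       labels = NULL) {
  if (is.null(dim(signals))) signals <- matrix(signals, ncol = 1)
  nsig <- ncol(signals); n <- nrow(signals)
  if (is.null(channels))
    channels <- if (nsig == 1) "C3-M2" else paste0("ch", seq_len(nsig))
  if (length(channels) != nsig) stop("one channel name per signal needed")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gains <- apply(signals, 2, function(x) {
    mx <- max(abs(x))
    if (mx == 0) 1 else 32000 / mx
  })
  adc <- round(sweep(signals, 2, gains, "*"))
  adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
  dat <- file.path(dir, paste0(name, ".dat"))
  con <- file(dat, "wb")
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  close(con)
  hea <- file.path(dir, paste0(name, ".hea"))
  lines <- c(sprintf("%s %d %g %d", name, nsig, fs, n),
             sprintf("%s.dat 16 %.6f(0)/adu 16 0 %d 0 0 %s",
                     name, gains, as.integer(adc[1, ]), channels))
  writeLines(lines, hea)
  if (!is.null(labels))
    writeLines(as.character(as.integer(labels)),
               file.path(dir, paste0(name, ".arousal")))
  invisible(hea)
}

#' Convenience WFDB writer for an `eeg_record`
#'
#' @param record an `eeg_record`.
#' @param dir output directory.
#' @param name record name; defaults to the record's id.
#' @return path to the .hea file, invisibly.
#' @export
write_wfdb_record <- function(record, dir, name = record$id) {
  write_wfdb(record$samples, record$sampling_rate, dir, name,
             channels = "C3-M2", labels = record$labels)
}

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("corrupt header: ", hea_path)
  nsig <- as.integer(top[2])
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gb <- f[3]  # gain(baseline)/units
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gb)))
    baseline <- if (grepl("\\(", gb))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gb)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
            else paste0("ch", NA)
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         desc = desc)
  })
  list(name = top[1], nsig = nsig, fs = as.numeric(top[3]),
       n = as.integer(top[4]), signals = sig)
}

#' Read a WFDB record into an `eeg_record`
#'
#' Reads the requested channel from a format-16 WFDB pair and converts
#' the 16-bit integers with the header's gain and baseline.  Arousal
#' labels are read from `<name>.arousal` (one 0/1 per sample) when
#' present, or from `label_path`; a record without labels gets all-zero
#' labels with a warning.
#'
#' @param path the .hea file, or the record prefix without extension.
#' @param channel channel description to select (default `"C3-M2"`).
#' @param label_path optional explicit label-vector file.
#' @return an `eeg_record`.
#' @export
read_wfdb_record <- function(path, channel = "C3-M2", label_path = NULL) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header not found: ", hea_path)
  h <- parse_hea(hea_path)
  descs <- vapply(h$signals, function(s) s$desc, character(1))
  ch <- which(descs == channel)
  if (length(ch) != 1)
    stop("channel '", channel, "' not found; available: ",
         paste(descs, collapse = ", "))
  if (h$signals[[ch]]$format != "16")
    stop("only format 16 is supported, got ", h$signals[[ch]]$format)
  dat <- file.path(dirname(hea_path), h$signals[[ch]]$file)
  con <- file(dat, "rb")
  raw16 <- readBin(con, "integer", n = h$n * h$nsig, size = 2,
                   endian = "little", signed = TRUE)
  close(con)
  adc <- matrix(raw16, ncol = h$nsig, byrow = TRUE)[, ch]
  x <- (adc - h$signals[[ch]]$baseline) / h$signals[[ch]]$gain
  lp <- label_path %||%
    file.path(dirname(hea_path), paste0(h$name, ".arousal"))
  if (file.exists(lp)) {
    labels <- as.integer(readLines(lp))
    if (length(labels) != h$n)
      stop("label file length ", length(labels), " != ", h$n, " samples")
  } else {
    warning("no arousal annotation found for ", h$name,
            "; labels set to all zero")
    labels <- integer(h$n)
  }
  eeg_record(x, labels, h$fs, id = h$name)
}
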