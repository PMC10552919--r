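#' Construct a multichannel EEG recording
#'
#' @param channels A [channel_set].
#' @param data C x T numeric matrix (microvolts), rows ordered as
#'   `channels$names`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(channels, data, fs) {
  stopifnot(inherits(channels, "channel_set"))
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != channels$C) stop("data must have one row per channel")
  if (ncol(data) < 1L) stop("recording must contain at least one sample")
  if (any(!is.finite(data))) stop("recording data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  rownames(data) <- channels$names
  structure(list(channels = channels, data = data, fs = as.numeric(fs)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$channels$C, " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", signif(ncol(x$data) / x$fs, 4), " s)\n", sep = "")
  invisible(x)
}

#' Read a recording from disk
#'
#' Two formats are supported. `"delim"` is a plain-text matrix with
#' channels as rows: a header row of sample indices, a first column of
#' channel labels, and a `# fs=<Hz>` comment line carrying the sampling
#' rate (tab-separated; see [write_recording()]). `"edf"` reads European
#' Data Format files with a uniform sampling rate across signals.
#'
#' @param path Input file.
#' @param format `"delim"`, `"edf"`, or `"auto"` (by file extension).
#' @param fs Sampling rate override for delimited files lacking the
#'   `# fs=` line.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "delim", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delim"
  }
  if (format == "edf") return(read_edf(path))
  ln1 <- readLines(path, n = 1L)
  file_fs <- NULL
  skip <- 0L
  if (startsWith(ln1, "#")) {
    m <- regmatches(ln1, regexec("fs\\s*=\\s*([0-9.eE+-]+)", ln1))[[1]]
    if (length(m) == 2L) file_fs <- as.numeric(m[2])
    skip <- 1L
  }
  fs <- if (!is.null(fs)) fs else file_fs
  if (is.null(fs) || !is.finite(fs))
    stop("sampling rate missing: no '# fs=' line in ", path, " and no fs argument")
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("delimited recording needs a label column and data: ", path)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric payload in ", path)
  eeg_recording(channel_set(labels), mat, fs)
}

#' Write a recording as a delimited matrix
#'
#' Channels as rows, header row of sample indices, first column of channel
#' labels, and a leading `# fs=<Hz>` comment. Round-trips through
#' [read_recording()] to full double precision.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", rec$fs), con)
  writeLines(paste(c("channel", seq_len(ncol(rec$data))), collapse = "\t"), con)
  for (i in seq_len(nrow(rec$data))) {
    writeLines(paste(c(rec$channels$names[i], sprintf("%.17g", rec$data[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Average re-reference
#'
#' Subtracts the instantaneous cross-channel mean from every channel, so
#' each output column sums to zero. Idempotent.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @return The re-referenced `eeg_recording`.
#' @export
average_rereference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$channels$C < 2L) stop("average reference needs at least 2 channels")
  eeg_recording(rec$channels, sweep(rec$data, 2L, colMeans(rec$data)), rec$fs)
}

#' Zero-phase band-pass filter
#'
#' Cascaded forward-backward Butterworth filters: a 2nd-order high-pass at
#' `lo` followed by a 4th-order low-pass at `hi` (the default 0.1-30 Hz EEG
#' band). The cascade avoids the numerical fragility of a single band-pass
#' whose edges differ by more than two decades.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Band edges in Hz (defaults 0.1 and 30).
#' @return Filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, lo = 0.1, hi = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (hi >= nyq) stop("high edge ", hi, " Hz must be below Nyquist (", nyq, " Hz)")
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  hp <- signal::butter(2, lo / nyq, type = "high")
  lp <- signal::butter(4, hi / nyq, type = "low")
  out <- t(apply(rec$data, 1L, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  eeg_recording(rec$channels, out, rec$fs)
}

#' Resample a recording to half its sampling rate
#'
#' Anti-aliased polyphase resampling by a factor of 1/2; the output has
#' `floor(T/2)` samples at `fs/2` Hz.
#'
#' @param rec An `eeg_recording` with at least 2 samples.
#' @return Resampled `eeg_recording`.
#' @export
resample_half <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  T <- ncol(rec$data)
  if (T < 2L) stop("need at least 2 samples to resample")
  n_out <- T %/% 2L
  # linear-phase FIR anti-alias filter at half the new Nyquist; reflection
  # padding plus a centred convolution keeps the output zero-phase and free
  # of edge transients, and unit DC gain preserves constants exactly
  ord <- min(64L, 2L * ((T - 1L) %/% 2L))
  h <- signal::fir1(ord, 0.5)
  h <- h / sum(h)
  half <- ord %/% 2L
  out <- t(apply(rec$data, 1L, function(x) {
    pad <- c(x[pmin(1L + rev(seq_len(half)), T)], x,
             x[pmax(T - seq_len(half), 1L)])
    y <- stats::filter(pad, h, sides = 2)[(half + 1L):(half + T)]
    y[seq.int(1L, by = 2L, length.out = n_out)]
  }))
  if (n_out == 1L) out <- matrix(out, nrow = rec$channels$C)
  eeg_recording(rec$channels, out, rec$fs / 2)
}

#' Standard preprocessing chain
#'
#' Average re-reference, 0.1-30 Hz zero-phase band-pass, then half-rate
#' resampling — the preparation applied to every recording before segments
#' are cut.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Band edges passed to [bandpass_filter()].
#' @return Preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, lo = 0.1, hi = 30) {
  resample_half(bandpass_filter(average_rereference(rec), lo, hi))
}

#' Cut a recording into training segments
#'
#' Non-overlapping consecutive windows of length `L` (200 samples by
#' default). In each window one channel is designated bad — drawn uniformly
#' at random unless `target` fixes it — its values are stored as the label
#' and its row is zero-filled.
#'
#' @param rec An `eeg_recording` with at least `L` samples.
#' @param L Window length in samples (default 200).
#' @param seed Integer seed for the target draws.
#' @param target Optional fixed bad-channel index or name for every
#'   segment; `NULL` (default) draws one per window.
#' @return List of `eeg_segment`s (`floor(T/L)` of them).
#' @export
make_training_segments <- function(rec, L = 200L, seed = 1L, target = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- as.integer(L)
  T <- ncol(rec$data)
  if (T < L) stop("recording too short: ", T, " samples < window length ", L)
  C <- rec$channels$C
  if (!is.null(target)) target <- resolve_channel(rec$channels, target)
  set.seed(as.integer(seed))
  n <- T %/% L
  lapply(seq_len(n), function(i) {
    win <- rec$data[, ((i - 1L) * L + 1L):(i * L), drop = FALSE]
    t <- if (is.null(target)) sample(C, 1L) else target
    label <- win[t, ]
    win[t, ] <- 0
    eeg_segment(win, t, label, rec$channels$names)
  })
}

#' Cut a recording into multi-bad-channel test cases
#'
#' Non-overlapping windows of length `L` (2000 samples by default); in each
#' window `n_bad` distinct channels are drawn uniformly, their rows
#' zero-filled and their originals kept as labels.
#'
#' @param rec An `eeg_recording`.
#' @param L Window length in samples (default 2000).
#' @param n_bad Number of simultaneous bad channels (1 to C-2).
#' @param seed Integer seed for the bad-set draws.
#' @return List of cases; each is a list with `input` (C x L, bad rows
#'   zero), `bad_set` (integer indices) and `labels` (n_bad x L matrix,
#'   rownames = channel names).
#' @export
make_test_cases <- function(rec, L = 2000L, n_bad = 1L, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- as.integer(L); n_bad <- as.integer(n_bad)
  T <- ncol(rec$data); C <- rec$channels$C
  if (T < L) stop("recording too short: ", T, " samples < window length ", L)
  if (n_bad < 1L || n_bad > C - 2L)
    stop("n_bad must be between 1 and C-2 = ", C - 2L)
  set.seed(as.integer(seed))
  n <- T %/% L
  lapply(seq_len(n), function(i) {
    win <- rec$data[, ((i - 1L) * L + 1L):(i * L), drop = FALSE]
    bad <- sort(sample(C, n_bad))
    labels <- win[bad, , drop = FALSE]
    rownames(labels) <- rec$channels$names[bad]
    win[bad, ] <- 0
    list(input = win, bad_set = bad, labels = labels)
  })
}
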