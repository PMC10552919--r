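# Minimal European Data Format (EDF) support: continuous recordings with a
# uniform sampling rate across signals, 16-bit samples, physical scaling per
# the signal headers. Annotation signals and discontinuous files are out of
# scope.

read_fixed <- function(con, n) {
  raw <- readBin(con, "raw", n)
  if (length(raw) != n) stop("truncated EDF header")
  trimws(rawToChar(raw))
}

#' Read an EDF file
#'
#' Supports continuous EDF recordings in which every signal shares one
#' sampling rate. Digital values are mapped to physical units using each
#' signal's physical/digital ranges.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_fixed(con, 8)
  if (version != "0") stop("unsupported EDF version '", version, "' in ", path)
  read_fixed(con, 80)  # patient id
  read_fixed(con, 80)  # recording id
  read_fixed(con, 8); read_fixed(con, 8)  # start date, time
  header_bytes <- as.integer(read_fixed(con, 8))
  read_fixed(con, 44)  # reserved
  n_rec <- as.integer(read_fixed(con, 8))
  rec_dur <- as.numeric(read_fixed(con, 8))
  ns <- as.integer(read_fixed(con, 4))
  if (is.na(ns) || ns < 1L) stop("EDF file declares no signals: ", path)
  field <- function(width) vapply(seq_len(ns), function(i) read_fixed(con, width), "")
  labels <- field(16)
  field(80)            # transducer
  field(8)             # physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)            # prefiltering
  spr <- as.integer(field(8))
  field(32)            # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported: ", path)
  if (rec_dur <= 0) stop("non-positive data-record duration in ", path)
  fs <- spr[1] / rec_dur
  seek(con, header_bytes)
  if (n_rec < 0L) {  # unknown record count: infer from file size
    n_rec <- as.integer((file.size(path) - header_bytes) / (2 * ns * spr[1]))
  }
  vals <- readBin(con, "integer", n = n_rec * ns * spr[1], size = 2,
                  signed = TRUE, endian = "little")
  if (length(vals) != n_rec * ns * spr[1]) stop("truncated EDF data in ", path)
  # records x (signal-major blocks of spr samples)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  dim(vals) <- c(spr[1], ns, n_rec)
  for (s in seq_len(ns)) data[s, ] <- as.vector(vals[, s, ])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- data * scale + (phys_min - dig_min * scale)
  eeg_recording(channel_set(labels), data, fs)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write an EDF file
#'
#' Writes a continuous EDF with one data record per second (or one record
#' total when the recording is shorter). Data are scaled to the 16-bit
#' digital range; quantization limits the round-trip accuracy to about
#' 1/65000 of each channel's amplitude range.
#'
#' @param rec An `eeg_recording` whose `fs` is a positive integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  T <- ncol(rec$data); ns <- rec$channels$C
  spr <- as.integer(min(fs, T))
  n_rec <- T %/% spr
  keep <- n_rec * spr
  data <- rec$data[, seq_len(keep), drop = FALSE]
  phys_min <- apply(data, 1, min); phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8), pad_field("X", 80), pad_field("X", 80),
                pad_field("01.01.00", 8), pad_field("00.00.00", 8),
                pad_field(256 * (1 + ns), 8), pad_field("", 44),
                pad_field(n_rec, 8), pad_field(format(spr / fs), 8),
                pad_field(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channels$names, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_min), pad_field, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_max), pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((data - phys_min) / scale + dig_min)
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1L) * spr + 1L):(r * spr), drop = FALSE]
    writeBin(as.integer(t(block)[seq_len(spr * ns) ]), con, size = 2, endian = "little")
  }
  invisible(path)
}
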