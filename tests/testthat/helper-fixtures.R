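# small shared fixtures, all generated in code

tiny_channels <- function(C = 4L) channel_set(paste0("ch", seq_len(C)))

# a model whose embeddings we control exactly
manual_model <- function(E, gain = rep(1, nrow(E)), bias = rep(0, nrow(E))) {
  ch <- tiny_channels(nrow(E))
  m <- amacw_model(ch, ncol(E), seed = 1)
  m$embeddings <- E
  rownames(m$embeddings) <- ch$names
  m$gain <- stats::setNames(as.numeric(gain), ch$names)
  m$bias <- stats::setNames(as.numeric(bias), ch$names)
  m
}

# segment with explicit data; target row is zeroed, original kept as label
manual_segment <- function(data, target) {
  label <- data[target, ]
  data[target, ] <- 0
  eeg_segment(data, target, label)
}

sine_recording <- function(freqs, fs = 500, T = 5000, names = NULL) {
  tt <- seq_len(T) / fs
  data <- t(vapply(freqs, function(f) sin(2 * pi * f * tt), numeric(T)))
  if (is.null(names)) names <- paste0("s", seq_along(freqs))
  eeg_recording(channel_set(names), data, fs)
}
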