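#' Synthetic-recording configuration
#'
#' Parameters of the EEG-like generator: `K` shared band-limited sources
#' mixed into `C` channels through a signed gain matrix (volume conduction
#' with dipole-sign flips, so some channel pairs are strongly negatively
#' correlated), plus independent band-limited sensor noise.
#'
#' @param C Channel count (default 17, the packaged 10-20 montage).
#' @param K Source count (default 4).
#' @param T Samples (default 20000).
#' @param fs Sampling rate in Hz (default 200).
#' @param mixing C x K signed gain matrix, or `"auto"`: gains decay with
#'   great-circle distance from a random source site on the packaged
#'   montage and flip sign across a random dipole plane.
#' @param noise_sd Sensor-noise standard deviation in microvolts
#'   (default 2).
#' @param source_kind `"ar2"` (default; AR(2) with a ~10 Hz resonance),
#'   `"bandlimited"` (low-passed white noise) or `"sines"` (random sinusoid
#'   mixture below 30 Hz).
#' @param source_scale Per-source standard deviation in microvolts
#'   (default 20).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(C = 17L, K = 4L, T = 20000L, fs = 200,
                         mixing = "auto", noise_sd = 2,
                         source_kind = c("ar2", "bandlimited", "sines"),
                         source_scale = 20, seed = 1L) {
  source_kind <- match.arg(source_kind)
  C <- as.integer(C); K <- as.integer(K); T <- as.integer(T)
  if (K < 1L) stop("need at least one source")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!identical(mixing, "auto")) {
    mixing <- as.matrix(mixing)
    if (!all(is.finite(mixing))) stop("mixing gains must be finite")
    if (nrow(mixing) != C || ncol(mixing) != K)
      stop("mixing must be a ", C, " x ", K, " matrix")
  }
  structure(list(C = C, K = K, T = T, fs = fs, mixing = mixing,
                 noise_sd = noise_sd, source_kind = source_kind,
                 source_scale = source_scale, seed = as.integer(seed)),
            class = "synth_config")
}

# zero-phase low-pass below `hi` Hz used to band-limit sources and noise
.lp30 <- function(x, fs, hi = 30) {
  if (hi >= fs / 2) return(x)
  lp <- signal::butter(4, hi / (fs / 2), type = "low")
  signal::filtfilt(lp, x)
}

gen_source <- function(kind, T, fs) {
  x <- switch(kind,
    ar2 = {
      # AR(2) resonance near 10 Hz: poles r*exp(+-i*2*pi*10/fs), r = 0.95
      w <- 2 * pi * 10 / fs
      as.vector(stats::arima.sim(list(ar = c(2 * 0.95 * cos(w), -0.95^2)), T))
    },
    bandlimited = stats::rnorm(T),
    sines = {
      f <- stats::runif(5, 1, 25)
      ph <- stats::runif(5, 0, 2 * pi)
      a <- stats::runif(5, 0.5, 1)
      tt <- seq_len(T) / fs
      colSums(a * sin(outer(2 * pi * f, tt) + ph)) + 0.2 * stats::rnorm(T)
    })
  x <- .lp30(x, fs)
  x / stats::sd(x)
}

auto_mixing <- function(C, K, montage) {
  pos <- montage$positions[seq_len(C), , drop = FALSE]
  M <- matrix(0, C, K)
  for (k in seq_len(K)) {
    center <- pos[sample(C, 1L), ]
    d <- acos(pmin(pmax(pos %*% center, -1), 1))   # great-circle distance
    gain <- exp(-d / 0.8)
    normal <- stats::rnorm(3)
    normal <- normal / sqrt(sum(normal^2))
    sgn <- ifelse(as.vector(pos %*% normal) >= 0, 1, -1)  # dipole plane
    M[, k] <- as.vector(gain) * sgn
  }
  M
}

#' Generate an EEG-like synthetic recording
#'
#' `data = mixing %*% sources * source_scale + noise`, with sources and
#' noise band-limited below 30 Hz so the standard preprocessing band-pass
#' is approximately a no-op on generated data. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return An `eeg_recording` with attribute `"mixing"` (the gain matrix
#'   actually used) and, when the channel count matches the packaged
#'   montage, channel names/positions from it.
#' @export
generate_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  montage <- standard_montage_1020()
  ch <- if (cfg$C <= montage$C) {
    channel_set(montage$names[seq_len(cfg$C)],
                montage$positions[seq_len(cfg$C), , drop = FALSE])
  } else {
    channel_set(paste0("ch", seq_len(cfg$C)))
  }
  M <- if (identical(cfg$mixing, "auto")) {
    if (is.null(ch$positions))
      stop("'auto' mixing needs montage positions; supply an explicit mixing matrix")
    auto_mixing(cfg$C, cfg$K, ch)
  } else cfg$mixing
  S <- t(vapply(seq_len(cfg$K), function(k) gen_source(cfg$source_kind, cfg$T, cfg$fs),
                numeric(cfg$T)))
  data <- M %*% S * cfg$source_scale
  if (cfg$noise_sd > 0) {
    noise <- t(vapply(seq_len(cfg$C),
                      function(i) .lp30(stats::rnorm(cfg$T), cfg$fs),
                      numeric(cfg$T)))
    noise <- noise / apply(noise, 1, stats::sd) * cfg$noise_sd
    data <- data + noise
  }
  rec <- eeg_recording(ch, data, cfg$fs)
  attr(rec, "mixing") <- M
  rec
}

#' Fixture: target channel is a known linear mix of the others
#'
#' Recovery oracle for training: channels 1..C-1 are independent
#' band-limited signals, and the last channel (the target) equals
#' `sum(weights_true[j] * channel_j) + noise`. Training on segments with
#' this target should recover `weights_true` (which must have unit
#' absolute sum, matching the model's weight constraint).
#'
#' @param C Channel count (target is channel `C`).
#' @param weights_true Length C-1 signed vector with `sum(abs(.)) == 1`.
#' @param T Samples (default 8000).
#' @param noise_sd Noise standard deviation on the target row
#'   (default 0.01; sources have unit variance).
#' @param seed Integer seed.
#' @param fs Sampling rate (default 200).
#' @return List with `recording` (an `eeg_recording`), `target` (= C) and
#'   `weights_true`.
#' @export
linear_target_fixture <- function(C = 17L, weights_true = c(0.6, 0.4, rep(0, C - 3L)),
                                  T = 8000L, noise_sd = 0.01, seed = 1L, fs = 200) {
  C <- as.integer(C)
  weights_true <- as.numeric(weights_true)
  if (length(weights_true) != C - 1L)
    stop("weights_true must have length C-1 = ", C - 1L)
  if (abs(sum(abs(weights_true)) - 1) > 1e-9)
    stop("weights_true must have unit absolute sum")
  set.seed(as.integer(seed))
  S <- t(vapply(seq_len(C - 1L), function(k) gen_source("bandlimited", T, fs),
                numeric(T)))
  target_row <- as.vector(weights_true %*% S)
  if (noise_sd > 0) target_row <- target_row + stats::rnorm(T, sd = noise_sd)
  data <- rbind(S, target_row)
  names <- c(paste0("good", seq_len(C - 1L)), "target")
  list(recording = eeg_recording(channel_set(names), data, fs),
       target = C, weights_true = weights_true)
}

#' Fixture: one channel nearly duplicates the target
#'
#' The scenario that motivates channel masking: channel 1 equals the target
#' plus small jitter, so an unregularized model concentrates all its weight
#' there; the remaining channels share a weaker common source with the
#' target, so a dispersed solution exists. Comparing the trained weight
#' concentration with and without masking exhibits the dispersion effect.
#'
#' @param C Channel count (target is channel `C`, duplicate is channel 1).
#' @param T Samples (default 8000).
#' @param jitter_sd Jitter standard deviation on the duplicate (default
#'   0.1; the shared source has unit variance).
#' @param seed Integer seed.
#' @param fs Sampling rate (default 200).
#' @return List with `recording`, `target` (= C) and `duplicate` (= 1).
#' @export
near_duplicate_fixture <- function(C = 8L, T = 8000L, jitter_sd = 0.1,
                                   seed = 1L, fs = 200) {
  C <- as.integer(C)
  if (C < 4L) stop("fixture needs at least 4 channels")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  set.seed(as.integer(seed))
  s_target <- gen_source("bandlimited", T, fs)
  dup <- s_target + if (jitter_sd > 0) stats::rnorm(T, sd = jitter_sd) else 0
  a <- 0.6   # shared-source loading of the other channels
  others <- t(vapply(seq_len(C - 2L), function(k) {
    a * s_target + sqrt(1 - a^2) * gen_source("bandlimited", T, fs)
  }, numeric(T)))
  data <- rbind(dup, others, s_target)
  names <- c("dup", paste0("ch", seq_len(C - 2L)), "target")
  list(recording = eeg_recording(channel_set(names), data, fs),
       target = C, duplicate = 1L)
}
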