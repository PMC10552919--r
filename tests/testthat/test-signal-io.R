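test_that("delimited recordings round-trip and enforce the header contract", {
  set.seed(2)
  rec <- eeg_recording(tiny_channels(5), matrix(stats::rnorm(5 * 100), 5, 100), 250)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  rec2 <- read_recording(path)
  expect_equal(rec2$data, rec$data, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rec2$fs, 250)
  expect_identical(rec2$channels$names, rec$channels$names)

  # duplicate labels are a format error
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# fs=100", "channel\t1\t2", "a\t1\t2", "a\t3\t4"), dup)
  expect_error(read_recording(dup), "duplicate")

  # non-numeric payload is a format error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# fs=100", "channel\t1\t2", "a\t1\toops", "b\t3\t4"), bad)
  expect_error(read_recording(bad), "non-numeric")

  # missing sampling rate is an error unless supplied
  nofs <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("channel\t1\t2", "a\t1\t2", "b\t3\t4"), nofs)
  expect_error(read_recording(nofs), "sampling rate")
  expect_equal(read_recording(nofs, fs = 128)$fs, 128)
})

test_that("EDF files written by the package read back with correct header and data", {
  set.seed(3)
  ch <- standard_montage_1020()
  rec <- eeg_recording(ch, matrix(stats::rnorm(17 * 1500, sd = 40), 17, 1500), 500)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  rec2 <- read_edf(path)
  expect_equal(rec2$channels$C, 17)
  expect_equal(rec2$fs, 500)
  expect_identical(rec2$channels$names, ch$names)
  # 16-bit quantization: relative error bounded by the digital resolution
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  expect_lt(max(abs(rec2$data - rec$data) / qstep), 1.0)
  # auto format dispatch by extension
  expect_equal(read_recording(path)$channels$C, 17)
})

test_that("average re-reference zeroes column means and is idempotent", {
  rec <- eeg_recording(tiny_channels(2), rbind(c(1, 5), c(3, 1)), 100)
  rr <- average_rereference(rec)
  expect_equal(rr$data[, 1], c(-1, 1), ignore_attr = TRUE)
  expect_equal(max(abs(colMeans(rr$data))), 0, tolerance = 1e-12)
  rr2 <- average_rereference(rr)
  expect_equal(rr2$data, rr$data, tolerance = 1e-12)
  expect_error(average_rereference(eeg_recording(channel_set("a"), matrix(1, 1, 4), 10)),
               "at least 2")
})

test_that("band-pass keeps 10 Hz, rejects 60 Hz and DC", {
  rms <- function(x) sqrt(mean(x^2))
  fs <- 500; T <- 10000
  tt <- seq_len(T) / fs
  mk <- function(f) eeg_recording(tiny_channels(2),
                                  rbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt)), fs)
  out10 <- bandpass_filter(mk(10))
  expect_equal(rms(out10$data[1, ]) / rms(sin(2 * pi * 10 * tt)), 1, tolerance = 0.05)
  out60 <- bandpass_filter(mk(60))
  expect_lt(rms(out60$data[1, ]) / rms(sin(2 * pi * 60 * tt)), 0.2)
  # DC: long record, inspect the steady-state interior
  dc <- eeg_recording(tiny_channels(2), matrix(1, 2, 60 * fs), fs)
  outdc <- bandpass_filter(dc)
  interior <- outdc$data[1, (10 * fs):(50 * fs)]
  expect_lt(rms(interior), 0.05)
  expect_error(bandpass_filter(mk(10), hi = 300), "Nyquist")
})

test_that("half-rate resampling halves fs and preserves band-limited content", {
  fs <- 500
  rec <- sine_recording(c(10, 5), fs = fs, T = 2000)
  out <- resample_half(rec)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), 1000)
  # compare against the analytically decimated sine (odd samples kept)
  tt2 <- seq(1, 2000, by = 2) / fs
  ref <- sin(2 * pi * 10 * tt2)
  core <- 100:900
  expect_gt(stats::cor(out$data[1, core], ref[core]), 0.99)
  # constants resample to the same constant
  cst <- eeg_recording(tiny_channels(1), matrix(3.5, 1, 100), 100)
  expect_equal(resample_half(cst)$data[1, ], rep(3.5, 50), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("segmentation partitions the recording with zero-filled targets", {
  set.seed(9)
  rec <- eeg_recording(tiny_channels(6), matrix(stats::rnorm(6 * 1000), 6, 1000), 200)
  segs <- make_training_segments(rec, L = 200, seed = 4)
  expect_length(segs, 5)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    expect_equal(s$input[s$target, ], rep(0, 200))
    win <- rec$data[, ((i - 1) * 200 + 1):(i * 200)]
    expect_equal(s$label, win[s$target, ], ignore_attr = TRUE)
    restored <- s$input
    restored[s$target, ] <- s$label
    expect_equal(restored, win, ignore_attr = TRUE)
  }
  # seeded determinism of the target draws
  t1 <- vapply(make_training_segments(rec, 200, seed = 4), `[[`, 1L, "target")
  t2 <- vapply(make_training_segments(rec, 200, seed = 4), `[[`, 1L, "target")
  expect_identical(t1, t2)
  expect_error(make_training_segments(rec, L = 2000), "too short")
})

test_that("test cases zero-fill n_bad channels and keep their labels", {
  set.seed(10)
  rec <- eeg_recording(standard_montage_1020(),
                       matrix(stats::rnorm(17 * 4000), 17, 4000), 200)
  cases <- make_test_cases(rec, L = 2000, n_bad = 5, seed = 2)
  expect_length(cases, 2)
  for (cs in cases) {
    expect_length(cs$bad_set, 5)
    expect_true(all(cs$input[cs$bad_set, ] == 0))
    restored <- cs$input
    restored[cs$bad_set, ] <- cs$labels
    expect_false(any(restored[cs$bad_set, ] != cs$labels))
  }
  # restoring labels reproduces the original window exactly
  cs <- cases[[1]]
  win <- rec$data[, 1:2000]
  restored <- cs$input
  restored[cs$bad_set, ] <- cs$labels
  expect_equal(restored, win, ignore_attr = TRUE)
  expect_error(make_test_cases(rec, n_bad = 16), "n_bad")
})

test_that("preprocessing chain is deterministic", {
  set.seed(12)
  rec <- eeg_recording(tiny_channels(4), matrix(stats::rnorm(4 * 2000), 4, 2000), 200)
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$data, b$data)
  expect_equal(a$fs, 100)
  expect_equal(ncol(a$data), 1000)
})
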