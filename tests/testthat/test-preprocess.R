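test_that("band-pass keeps passband tones and attenuates stopband tones", {
  fs <- 128
  t <- (0:4095) / fs
  spec <- bandpass_spec(1, 40)
  rms <- function(x) sqrt(mean(x^2))

  tone10 <- ts_record(sin(2 * pi * 10 * t), fs = fs)
  out10 <- butterworth_bandpass(tone10, spec)
  expect_equal(rms(out10$samples) / rms(tone10$samples), 1, tolerance = 0.05)

  tone60 <- ts_record(sin(2 * pi * 60 * t), fs = fs)
  out60 <- butterworth_bandpass(tone60, spec)
  atten_db <- 20 * log10(rms(out60$samples) / rms(tone60$samples))
  expect_lt(atten_db, -20)
})

test_that("filtering is linear and preserves length and metadata", {
  set.seed(3)
  r <- ts_record(rnorm(1000), fs = 128, channel = "EEG05", session = 2,
                 stimulus_id = "third")
  spec <- bandpass_spec(1, 40)
  y1 <- butterworth_bandpass(r, spec)
  r5 <- r; r5$samples <- 5 * r$samples
  y5 <- butterworth_bandpass(r5, spec)
  expect_equal(y5$samples, 5 * y1$samples, tolerance = 1e-9)
  expect_length(y1$samples, 1000)
  expect_equal(y1$channel, "EEG05")
  expect_equal(y1$session, 2L)

  zero <- butterworth_bandpass(ts_record(rep(0, 500), fs = 128), spec)
  expect_equal(zero$samples, rep(0, 500))
})

test_that("zero-phase filtering does not shift a symmetric pulse", {
  fs <- 128
  n <- 1024
  center <- (n + 1) / 2
  pulse <- exp(-((seq_len(n) - center) / 20)^2)
  out <- butterworth_bandpass(ts_record(pulse, fs = fs),
                              bandpass_spec(1, 40))$samples
  expect_equal(which.max(abs(out)), floor(center), tolerance = 1)
  expect_lt(max(abs(out - rev(out))), 1e-3 * max(abs(out)))
})

test_that("invalid band or too-short signal is rejected", {
  expect_error(bandpass_spec(40, 1), "low_hz < high_hz")
  r <- ts_record(rnorm(100), fs = 128)
  expect_error(butterworth_bandpass(r, bandpass_spec(1, 70)), "Nyquist")
  short <- ts_record(rnorm(10), fs = 128)
  expect_error(butterworth_bandpass(short, bandpass_spec(1, 40)),
               "too short")
})

test_that("truncation takes the head and counts samples by floor", {
  r <- ts_record(rnorm(120 * 128), fs = 128)
  out <- truncate_record(r, 118.2)
  expect_length(out$samples, 15129)   # floor(118.2 * 128)
  expect_equal(out$samples, r$samples[1:15129])

  expect_equal(truncate_record(r, 120)$samples, r$samples)
  short <- ts_record(rnorm(100 * 128), fs = 128)
  expect_error(truncate_record(short, 118.2), "insufficient data")
})

test_that("channel exclusion drops labels and preserves order", {
  recs <- lapply(sprintf("EEG%02d", 1:14), function(ch)
    ts_record(rnorm(10), fs = 128, channel = ch))
  kept <- exclude_channels(recs, c("EEG03", "EEG11"))
  expect_length(kept, 12)
  expect_equal(vapply(kept, function(r) r$channel, ""),
               sprintf("EEG%02d", setdiff(1:14, c(3, 11))))
  expect_identical(exclude_channels(recs, character(0)), recs)
  expect_warning(exclude_channels(recs, "EMG01"), "not present")
  expect_warning(out <- exclude_channels(recs, sprintf("EEG%02d", 1:14)),
                 "all channels")
  expect_length(out, 0)
})
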