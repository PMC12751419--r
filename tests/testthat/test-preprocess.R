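test_that("the ECG bandpass rejects DC and keeps the passband", {
  fs <- 125
  t <- (0:7499) / fs
  # DC lies outside the 0.4-45 Hz band
  dc <- bandpass(rep(1, 7500), fs, preset = "ecg")
  expect_lt(max(abs(dc)), 0.01)
  # 1 Hz is well inside the band
  s1 <- bandpass(sin(2 * pi * 1 * t), fs, preset = "ecg")
  expect_gte(max(s1[2000:5500]), 0.9)
  # 50 Hz is above the 45 Hz edge
  s50 <- bandpass(sin(2 * pi * 50 * t), fs, preset = "ecg")
  expect_lte(max(abs(s50[2000:5500])), 0.5)
})

test_that("the PPG preset passes heart-rate frequencies and cuts 20 Hz", {
  fs <- 125
  t <- (0:7499) / fs
  s1 <- bandpass(sin(2 * pi * 1.2 * t), fs, preset = "ppg")
  expect_gte(max(s1[2000:5500]), 0.9)
  s20 <- bandpass(sin(2 * pi * 20 * t), fs, preset = "ppg")
  expect_lte(max(abs(s20[2000:5500])), 0.1)
})

test_that("bandpass validates its band edges and is near-idempotent", {
  expect_error(bandpass(rnorm(100), 125, lo = 1, hi = 80), "Nyquist")
  expect_error(bandpass(rnorm(100), 125, lo = 5, hi = 2), "lo < hi")
  # idempotence up to passband ripple, judged on an in-band signal (white
  # noise keeps energy at the band edges where |H|^2 vs |H|^4 differ)
  t <- (0:3999) / 125
  x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 7 * t) +
    0.3 * sin(2 * pi * 25 * t)
  y1 <- bandpass(x, 125, preset = "ecg")
  y2 <- bandpass(y1, 125, preset = "ecg")
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.01)
})

test_that("zero-phase filtering leaves peak positions in place", {
  pair <- make_pair("rsr", duration_s = 20, seed = 4)
  pk_raw <- detect_peaks(pair$ecg, 125)$indices
  pk_f <- detect_peaks(bandpass(pair$ecg, 125, preset = "ecg"), 125)$indices
  k <- min(length(pk_raw), length(pk_f))
  expect_true(all(abs(pk_raw[1:k] - pk_f[1:k]) <= 1))
})

test_that("resampling preserves length ratio and tone frequency", {
  x <- sin(2 * pi * 2 * (0:2399) / 300)
  expect_identical(resample_signal(x, 300, 300), x)
  y <- resample_signal(x, 300, 125)
  expect_length(y, 1000)
  # FFT-peak oracle: the dominant bin is still 2 Hz at the new rate
  sp <- Mod(fft(y))[1:500]
  f_axis <- (0:499) * 125 / 1000
  expect_equal(f_axis[which.max(sp)], 2)
})

test_that("first-peak alignment removes a pure transmission delay", {
  x <- numeric(1000)
  x[c(100, 300, 500, 700, 900)] <- 1
  # already aligned: unchanged
  al0 <- align_first_peaks(x, x, 125)
  expect_identical(al0$ecg, x)
  expect_identical(al0$ppg, x)
  # delayed copy: both shortened by the delay, first peaks coincide
  k <- 40L
  y <- c(numeric(k), x)[1:1000]
  al <- align_first_peaks(x, y, 125)
  expect_length(al$ecg, 1000 - k)
  expect_equal(which(al$ecg == 1)[1], which(al$ppg == 1)[1])
  expect_error(align_first_peaks(x, rep(0, 1000), 125), "peak")
})

test_that("segmentation uses half-open windows with tail dropping", {
  s <- segment_signal(seq_len(1024), window = 512, overlap = 0.5)
  expect_equal(s$starts, c(1L, 257L, 513L))
  expect_equal(nrow(s$segments), 3)
  expect_equal(s$segments[1, ], 1:512)
  expect_equal(s$segments[3, ], 513:1024)

  expect_equal(nrow(segment_signal(seq_len(512))$segments), 1)
  expect_equal(nrow(segment_signal(seq_len(511))$segments), 0)

  # interior samples are covered exactly 1/(1-overlap) times
  s2 <- segment_signal(seq_len(2048), 512, 0.5)
  cover <- numeric(2048)
  for (i in seq_along(s2$starts)) {
    idx <- s2$starts[i]:(s2$starts[i] + 511)
    cover[idx] <- cover[idx] + 1
  }
  expect_true(all(cover[513:1536] == 2))
  expect_error(segment_signal(1:100, window = 0), "window")
  expect_error(segment_signal(1:100, overlap = 1), "overlap")
})

test_that("min-max scaling maps records onto [-1, 1]", {
  expect_equal(minmax_scale(c(0, 1, 2)), c(-1, 0, 1))
  x <- c(-1, 0.3, 1)
  expect_equal(minmax_scale(x), x)
  expect_warning(z <- minmax_scale(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(2)
  y <- minmax_scale(rnorm(100))
  expect_equal(range(y), c(-1, 1))
})
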