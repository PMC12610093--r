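test_that("band-pass keeps in-band power and rejects out-of-band power", {
  in_band <- tone_trialset(10)
  out <- bandpass_filter(in_band, 0.5, 100)
  expect_gte(signal_power(out), 0.9 * signal_power(in_band))

  out_band <- tone_trialset(120)
  rej <- bandpass_filter(out_band, 0.5, 100)
  expect_lte(signal_power(rej), 0.05 * signal_power(out_band))

  dc <- eeg_trialset(array(5, c(1, 1, 2048)), 1, 256)
  hp <- bandpass_filter(dc, 0.5, 100)
  expect_lt(mean(abs(hp$data)), 0.01 * 5)

  expect_error(bandpass_filter(in_band, 0.5, 130), "Nyquist")
})

test_that("notch removes line frequency and preserves the passband", {
  line <- tone_trialset(50)
  expect_lte(signal_power(notch_filter(line, 50)), 0.05 * signal_power(line))
  tone <- tone_trialset(10)
  expect_gte(signal_power(notch_filter(tone, 50)), 0.9 * signal_power(tone))
  zero <- eeg_trialset(array(0, c(1, 1, 256)), 1, 256)
  expect_equal(notch_filter(zero, 50)$data, zero$data)
  expect_error(notch_filter(tone, 200), "Nyquist")
})

test_that("filters are linear operators", {
  set.seed(4)
  x <- array(rnorm(1 * 1 * 512), c(1, 1, 512))
  y <- array(rnorm(1 * 1 * 512), c(1, 1, 512))
  mk <- function(a) eeg_trialset(a, 1, 256)
  for (op in list(function(ts) bandpass_filter(ts, 1, 40),
                  function(ts) notch_filter(ts, 50))) {
    lhs <- op(mk(2 * x + 3 * y))$data
    rhs <- 2 * op(mk(x))$data + 3 * op(mk(y))$data
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
  }
})

test_that("re-referencing subtracts the mean of the reference channels", {
  ts <- random_trialset(n = 2, ch = 4, t = 16, seed = 8)
  # single reference channel becomes identically zero
  r1 <- rereference(ts, 3)
  expect_equal(max(abs(r1$data[, 3, ])), 0)
  # a common offset is removed from every channel
  off <- ts
  off$data <- off$data + 7
  expect_equal(rereference(off, 2)$data, rereference(ts, 2)$data)
  # two reference channels: their mean is subtracted everywhere
  r2 <- rereference(ts, c(1, 2))
  manual <- ts$data[1, 4, 5] - (ts$data[1, 1, 5] + ts$data[1, 2, 5]) / 2
  expect_equal(r2$data[1, 4, 5], manual)
  # empty reference set is the identity
  expect_identical(rereference(ts, integer(0)), ts)
  expect_error(rereference(ts, 9), "out of range")
})

test_that("downsampling follows the length rule and preserves band content", {
  tt <- (0:4095) / 1024
  ts <- eeg_trialset(array(sin(2 * pi * 4 * tt), c(1, 1, 4096)), 1, 1024)
  ds <- downsample(ts, 256)
  expect_equal(n_timepoints(ds), 1024)   # round(4096 * 256 / 1024)
  expect_equal(ds$sampling_rate, 256)

  expect_identical(downsample(ts, 1024), ts)

  t2 <- (0:999) / 1000
  s4 <- eeg_trialset(array(sin(2 * pi * 4 * t2), c(1, 1, 1000)), 1, 1000)
  d4 <- downsample(s4, 250)
  ideal <- sin(2 * pi * 4 * (0:249) / 250)
  expect_gte(cor(d4$data[1, 1, ], ideal), 0.99)

  expect_error(downsample(ts, -1), "positive")
  expect_error(downsample(ds, 512), "exceeds")
})

test_that("z-score statistics pool per channel over trials and time", {
  x <- array(0, c(2, 1, 1))
  x[1, 1, 1] <- 1; x[2, 1, 1] <- 3
  two <- eeg_trialset(x, c(1, 1), 10)
  st <- zscore_fit(two)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)  # population divisor

  zeros <- eeg_trialset(array(0, c(2, 1, 8)), c(1, 1), 10)
  expect_warning(st0 <- zscore_fit(zeros), "constant")
  expect_equal(st0$mean, 0)
  expect_equal(st0$sd, 1e-8)

  ts <- random_trialset(n = 8, seed = 2)
  st2 <- zscore_fit(ts)
  z <- zscore_apply(ts, st2)
  for (c in seq_len(n_channels(ts))) {
    v <- as.vector(z$data[, c, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  }
})

test_that("z-score application is an affine per-channel map", {
  ts <- random_trialset(n = 2, ch = 2, t = 4, seed = 6)
  st <- structure(list(mean = c(2, 0), sd = c(1, 1)), class = "zscore_stats")
  z <- zscore_apply(ts, st)
  expect_equal(z$data[, 1, ], ts$data[, 1, ] - 2)
  expect_equal(z$data[, 2, ], ts$data[, 2, ])
  ident <- structure(list(mean = c(0, 0), sd = c(1, 1)), class = "zscore_stats")
  expect_equal(zscore_apply(ts, ident)$data, ts$data)
  expect_error(zscore_apply(ts, structure(list(mean = 0, sd = 1),
                                          class = "zscore_stats")), "channels")
})

test_that("z-score fitting never sees held-out data", {
  ts <- random_trialset(n = 10, seed = 12)
  train_idx <- 1:6
  st <- zscore_fit(subset_trials(ts, train_idx))
  perturbed <- ts
  perturbed$data[7:10, , ] <- perturbed$data[7:10, , ] * 100 + 17
  st2 <- zscore_fit(subset_trials(perturbed, train_idx))
  expect_identical(st, st2)
})

test_that("preprocessing preserves trial count and labels", {
  ts <- random_trialset(n = 5, ch = 4, t = 512, fs = 256, seed = 3)
  out <- preprocess(ts, preprocess_config(bandpass_low = 1, bandpass_high = 40,
                                          notch_freq = 50, target_rate = 128,
                                          reference_channels = 1))
  expect_equal(n_trials(out), 5)
  expect_identical(out$labels, ts$labels)
  expect_equal(out$sampling_rate, 128)
  expect_equal(n_timepoints(out), 256)
})
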