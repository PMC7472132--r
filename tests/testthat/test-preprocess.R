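# Conditioning chain: resampling, zero-phase band-pass, segmentation,
# edge trimming.

test_that("resampling honors the length contract and preserves tones", {
  x <- rnorm(10000)
  y <- resample_signal(x, 1000, 256)
  expect_length(y, 2560)
  expect_identical(resample_signal(x, 500, 500), x)
  expect_length(resample_signal(numeric(0), 1000, 256), 0)

  # 5 Hz tone survives 1000 -> 256 Hz with its periodogram peak intact
  t <- (0:9999) / 1000
  tone <- sin(2 * pi * 5 * t)
  z <- resample_signal(tone, 1000, 256)
  p <- welch_psd(z, 256, segment_s = 4)
  peak_hz <- p$freq[which.max(p$psd)]
  expect_lt(abs(peak_hz - 5), 256 / 1024 + 1e-9)   # within one bin
})

test_that("resample round trip preserves band-limited RMS within 1%", {
  t <- (0:9999) / 1000
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 18 * t)
  y <- resample_signal(resample_signal(x, 1000, 256), 256, 1000)
  core <- 500:9500   # ignore resampler edge taper
  expect_lt(abs(sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2)) - 1), 0.01)
})

test_that("band-pass has the specified passband and stopband behavior", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  core <- (2 * fs):(18 * fs)

  inband <- sin(2 * pi * 10 * t)
  out <- bandpass(inband, fs)
  amp <- sqrt(2 * mean(out[core]^2))
  expect_gte(amp, 0.89)
  expect_lte(amp, 1.12)

  dc <- rep(1, length(t))
  expect_lt(max(abs(bandpass(dc, fs))), 1e-3)

  drift <- sin(2 * pi * 0.2 * t)
  att <- sqrt(mean(bandpass(drift, fs)[core]^2)) / sqrt(mean(drift[core]^2))
  expect_lt(20 * log10(att), -20)

  expect_error(bandpass(inband, 40), "fs")
})

test_that("band-pass is zero-phase and nearly idempotent in band", {
  fs <- 256
  rec <- generate_ecg(ecg_model_params(), 10, seed = 5)
  once <- bandpass(rec$samples, fs)
  twice <- bandpass(once, fs)
  core <- 257:2304
  expect_lt(abs(sqrt(mean(twice[core]^2)) / sqrt(mean(once[core]^2)) - 1),
            0.05)
  expect_length(once, length(rec$samples))
})

test_that("segmentation drops the remainder and trims edges exactly", {
  fs <- 256
  segs <- segment(rnorm(60 * fs), fs, 10)
  expect_length(segs, 6)
  expect_true(all(lengths(segs) == 2560))
  expect_length(segment(rnorm(round(9.5 * fs)), fs, 10), 0)
  expect_length(segment(rnorm(25 * fs), fs, 10), 2)

  x <- rnorm(2560)
  tr <- trim_edges(x, fs, 1)
  expect_length(tr, 2048)
  expect_identical(tr, x[257:2304])
  expect_identical(trim_edges(x, fs, 0), x)
  expect_error(trim_edges(rnorm(400), fs, 1), "too short")
})

test_that("config invariants are enforced", {
  expect_error(preprocess_config(bp_low = 30, bp_high = 25), "bp_low")
  expect_error(preprocess_config(edge_trim_s = 6, segment_s = 10),
               "edge_trim_s")
})
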