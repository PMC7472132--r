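# Signal quality indices.

test_that("SNR improvement is the plain difference", {
  expect_equal(snr_improvement(4.01, 2.27), 1.74, tolerance = 1e-12)
  expect_equal(snr_improvement(3.3, 3.3), 0)
  expect_equal(snr_improvement(2.27, 4.01), -1.74, tolerance = 1e-12)
})

test_that("ratio of power isolates the 5-20 Hz band", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  expect_gt(ratio_of_power(sin(2 * pi * 10 * t), fs), 0.99)
  expect_lt(ratio_of_power(sin(2 * pi * 2 * t), fs), 0.05)

  # white noise: flat PSD, expected in-band fraction ~ 15/128
  vals <- vapply(1:20, function(s) {
    ratio_of_power(generate_colored_noise(noise_spec("white"), 8 * fs, fs,
                                          seed = s), fs)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 15 / 128), 0.02)

  expect_error(ratio_of_power(numeric(300), 256), "all-zero")
  expect_error(ratio_of_power(rnorm(100), 256), "1 s")
})

test_that("cross-correlation has Pearson zero-lag semantics", {
  x <- rnorm(1000)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  expect_equal(cross_correlation(x, 2 * x + 5), 1)

  fs <- 256
  t <- (0:(fs - 1)) / fs    # exactly 10 periods of a 10 Hz tone
  s10 <- sin(2 * pi * 10 * t); c10 <- cos(2 * pi * 10 * t)
  expect_lt(abs(cross_correlation(s10, c10)), 1e-10)
  expect_error(cross_correlation(x, rep(1, 1000)), "variance")

  # lag search recovers correlation lost to a small shift
  y <- c(rnorm(10), x)[1:1000]
  expect_gt(cross_correlation(x, y, max_lag_s = 0.1, fs = fs),
            0.99)
})

test_that("ratio of power and cross-correlation are scale invariant", {
  pair <- fixture_noise_pairs(1, seed0 = 50)[[1]]
  fs <- 256
  expect_equal(ratio_of_power(pair$noisy, fs),
               ratio_of_power(3.7 * pair$noisy, fs), tolerance = 1e-12)
  expect_equal(cross_correlation(pair$clean, pair$noisy),
               cross_correlation(pair$clean, 3.7 * pair$noisy),
               tolerance = 1e-12)
})

test_that("corruption lowers the ratio of power for every color and level", {
  fs <- 256
  grid <- default_noise_conditions()
  for (i in seq_len(nrow(grid))) {
    pair <- fixture_noise_pairs(1, color = grid$color[i],
                                snr_db = grid$snr_db[i],
                                seed0 = 60 + i)[[1]]
    expect_lt(ratio_of_power(pair$noisy, fs), ratio_of_power(pair$clean, fs))
  }
})

test_that("sqi_report assembles a consistent row", {
  pair <- fixture_noise_pairs(1, seed0 = 55)[[1]]
  rep <- sqi_report(pair$clean, pair$noisy, pair$clean, 256)
  expect_equal(rep$snr_imp_db, rep$snr_denoised_db - rep$snr_noisy_db)
  expect_identical(rep$snr_denoised_db, Inf)
  expect_true(rep$rop_clean >= 0 && rep$rop_clean <= 1)
})
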