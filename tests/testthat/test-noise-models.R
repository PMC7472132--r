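# Colored-noise synthesis, SNR calibration, and the motion-artifact
# surrogate.

test_that("colored-noise PSD slopes match their exponents across seeds", {
  alphas <- c(white = 0, pink = -1, brown = -2, blue = 1, purple = 2)
  for (col in names(alphas)) {
    for (s in 1:10) {
      y <- generate_colored_noise(noise_spec(col), 2560, 256, seed = s)
      expect_lt(abs(psd_slope(y, 256) - alphas[[col]]), 0.15)
      expect_lt(abs(mean(y)), 1e-10)
    }
  }
})

test_that("noise generation is deterministic and validates its inputs", {
  a <- generate_colored_noise(noise_spec("pink"), 512, 256, seed = 7)
  b <- generate_colored_noise(noise_spec("pink"), 512, 256, seed = 7)
  expect_identical(a, b)
  expect_error(noise_spec("mauve"), "color")
  expect_error(generate_colored_noise(noise_spec("pink"), 0, 256), "n_samples")
})

test_that("SNR calibration hits the target exactly for all colors and levels", {
  clean <- fixture_clean_record(seed = 2)$samples
  for (col in c("white", "pink", "brown", "blue", "purple")) {
    noise <- generate_colored_noise(noise_spec(col), length(clean), 256,
                                    seed = 5)
    for (target in c(-5, -7, -15, -17)) {
      cr <- scale_noise_to_snr(clean, noise, target)
      expect_lt(abs(cr$achieved_snr_db - target), 1e-6)
      expect_lt(abs(measure_snr(clean, cr$noisy) - target), 1e-6)
      # additivity: stored noise is the exact elementwise difference
      expect_identical(cr$noisy - cr$clean, cr$noise)
    }
  }
})

test_that("calibration scale agrees with a brute-force grid search", {
  clean <- c(1, 1, 1, 1)
  noise <- c(1, -1, 1, -1)
  target <- -15
  cr <- scale_noise_to_snr(clean, noise, target)
  # oracle: dense search over candidate scales for the SNR closest to target
  grid <- seq(0.1, 20, by = 1e-4)
  err <- abs(10 * log10(mean(clean^2) / (grid^2 * mean(noise^2))) - target)
  oracle_scale <- grid[which.min(err)]
  achieved_scale <- sqrt(mean(cr$noise^2) / mean(noise^2))
  expect_lt(abs(achieved_scale - oracle_scale), 1e-3)
  expect_error(scale_noise_to_snr(c(0, 0), c(1, 1), -5), "zero power")
  cr0 <- scale_noise_to_snr(clean, noise, 0)
  expect_equal(mean(cr0$noise^2), mean(clean^2), tolerance = 1e-12)
})

test_that("measure_snr matches hand arithmetic and handles zero residual", {
  ref <- c(2, 0, -2, 0)
  cor <- c(3, 1, -1, 1)
  # residual = (1,1,1,1): P_ref = 2, P_res = 1 -> 10 log10(2)
  expect_equal(measure_snr(ref, cor), 10 * log10(2), tolerance = 1e-12)
  expect_identical(measure_snr(ref, ref), Inf)
  # residual power equal to reference power -> 0 dB
  expect_equal(measure_snr(ref, ref + c(2, 0, 0, 2)), 0, tolerance = 1e-12)
  expect_error(measure_snr(c(0, 0), c(1, 1)), "zero power")
})

test_that("motion artifact surrogate obeys its spec", {
  zero <- motion_artifact_spec(wander_amp_mv = 0, burst_amp_mv = 0,
                               pop_amp_mv = 0)
  expect_true(all(generate_motion_artifact(zero, 1000, 256, seed = 1) == 0))

  wander <- motion_artifact_spec(wander_amp_mv = 0.8, wander_freq_hz = 0.3,
                                 burst_amp_mv = 0, pop_amp_mv = 0)
  y <- generate_motion_artifact(wander, 2560, 256, seed = 3)
  p <- welch_psd(y, 256, segment_s = 4)
  expect_lt(p$freq[which.max(p$psd)], 1)

  a <- generate_motion_artifact(motion_artifact_spec(), 2560, 256, seed = 9)
  b <- generate_motion_artifact(motion_artifact_spec(), 2560, 256, seed = 9)
  expect_identical(a, b)
  expect_error(motion_artifact_spec(burst_band_hz = c(60, 20)), "increasing")
  expect_error(generate_motion_artifact(motion_artifact_spec(), 100, 100),
               "fs / 2")
})
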