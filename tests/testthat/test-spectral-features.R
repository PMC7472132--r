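# STFT analysis/synthesis, context stacking, and normalization.

test_that("frame and bin geometry match the configuration", {
  x <- rnorm(2560)
  sp <- stft(x)
  expect_equal(dim(sp$frames), c(37, 129))
  expect_true(all(Mod(sp$frames) >= 0))
  expect_error(stft(rnorm(100)), "too short")

  z <- stft(numeric(2560))
  expect_true(all(Mod(z$frames) == 0))

  # unit impulse at sample 1: energy confined to frames overlapping it
  imp <- numeric(2560); imp[1] <- 1
  m <- magnitudes(stft(imp))
  expect_gt(sum(m[1, ]), 0)
  expect_true(all(m[5:37, ] == 0))
})

test_that("frame-count formula matches brute-force enumeration", {
  cfg <- stft_config()
  for (n in c(256, 257, 319, 320, 321, 1000, 2560, 9999, 10000)) {
    # oracle: count frames by walking the signal
    count <- 0L; at <- 1L
    while (at + cfg$n_fft - 1L <= n) { count <- count + 1L; at <- at + cfg$hop }
    expect_identical(nrow(stft(rnorm(n), cfg)$frames), count)
  }
})

test_that("iSTFT round trip is exact on the interior", {
  cfg <- stft_config()
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(2560)
    y <- istft(stft(x, cfg), cfg)
    interior <- (cfg$n_fft + 1):(2560 - cfg$n_fft)
    rel <- sqrt(mean((y[interior] - x[interior])^2)) /
      sqrt(mean(x[interior]^2))
    expect_lt(rel, 1e-10)
  }
  # magnitude + phase of the same signal recombine to the signal
  x <- rnorm(2560)
  sp <- stft(x, cfg)
  sp$frames <- Mod(sp$frames) * exp(1i * Arg(sp$frames))
  y <- istft(sp, cfg)
  interior <- 257:2304
  expect_lt(max(abs(y[interior] - x[interior])), 1e-10)
})

test_that("single-frame synthesis matches the direct overlap-add formula", {
  cfg <- stft_config()
  x <- rnorm(256)
  sp <- stft(x, cfg)
  y <- istft(sp, cfg)
  w <- cfg$window
  # oracle: with one frame, y = w * (w * x) / w^2 = x wherever w > 0
  expect_equal(y, x, tolerance = 1e-10)
})

test_that("per-frame Parseval energy identity holds", {
  cfg <- stft_config()
  x <- rnorm(2560)
  sp <- stft(x, cfg)
  for (j in c(1, 10, 37)) {
    at <- (j - 1) * cfg$hop + seq_len(cfg$n_fft)
    wx <- x[at] * cfg$window
    full <- stats::fft(wx)
    expect_equal(sum(Mod(full)^2) / cfg$n_fft, sum(wx^2), tolerance = 1e-8)
  }
})

test_that("context stacking slides one frame at a time", {
  m <- matrix(rnorm(37 * 129), nrow = 37)
  st <- stack_context(m, k = 8)
  expect_equal(dim(st$stacks), c(30, 129, 8))
  expect_equal(st$target_frames, 8:37)
  # content: stack i, slot j is frame i + j - 1
  expect_equal(st$stacks[3, , 5], m[7, ])
  st1 <- stack_context(m, k = 1)
  expect_equal(st1$stacks[, , 1], m)
  expect_error(stack_context(m[1:7, ], k = 8), "at least 8")
})

test_that("normalization is exact on the fitting set and invertible", {
  m <- matrix(abs(rnorm(50 * 129)), nrow = 50)
  ns <- fit_normalizer(m)
  z <- apply_norm(m, ns)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, function(c) mean(c^2) - mean(c)^2) - 1)), 1e-6)
  back <- invert_norm(z, ns)
  expect_lt(max(abs(back - m)) / max(abs(m)), 1e-12)

  # training stats applied to shifted data differ from that data's own stats
  m2 <- m + 3
  z2 <- apply_norm(m2, ns)
  own <- apply_norm(m2, fit_normalizer(m2))
  expect_gt(max(abs(colMeans(z2))), 1)       # not centered by foreign stats
  expect_lt(max(abs(colMeans(own))), 1e-9)

  # constant bins are floored, not an error
  mc <- m; mc[, 3] <- 5
  nsc <- fit_normalizer(mc)
  expect_gte(min(nsc$sd), 1e-8)
  expect_true(all(is.finite(apply_norm(mc, nsc))))
  expect_error(fit_normalizer(m[1, , drop = FALSE]), "2 frames")
})
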