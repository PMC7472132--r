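# Shared fixture builders. Everything is generated in code at test time.

# log-log PSD slope oracle: Welch estimate + least-squares regression
psd_slope <- function(y, fs) {
  p <- welch_psd(y, fs)
  sel <- p$freq >= 1 & p$freq <= 0.45 * fs
  unname(stats::coef(stats::lm(log10(p$psd[sel]) ~ log10(p$freq[sel])))[2])
}

fixture_clean_record <- function(seed = 1L, bpm = 60, duration_s = 10,
                                 fs = 256) {
  rec <- generate_ecg(ecg_model_params(fs = fs, heart_rate_bpm = bpm),
                      duration_s, seed = seed)
  rec$samples <- bandpass(rec$samples, fs)
  rec
}

# clean/noisy pairs corrupted with calibrated colored noise
fixture_noise_pairs <- function(n, color = "white", snr_db = -5,
                                seed0 = 1L, fs = 256) {
  lapply(seq_len(n), function(i) {
    rec <- fixture_clean_record(seed = seed0 + i, bpm = 60 + (i %% 5) * 8)
    noise <- generate_colored_noise(noise_spec(color),
                                    length(rec$samples), fs,
                                    seed = 1000L + seed0 + i)
    list(clean = rec$samples,
         noisy = scale_noise_to_snr(rec$samples, noise, snr_db)$noisy,
         r_peaks = rec$r_peaks)
  })
}

# a trained model whose prediction is the identity on its target frame:
# single 1-wide convolution selecting input channel k, no batch norm
fixture_identity_model <- function(stats, k = 8L, n_bins = 129L) {
  cfg <- rced_config(filter_counts = 1L, kernel_widths = 1L,
                     n_bins = n_bins, context_k = k)
  model <- build_rced(cfg, seed = 1L)
  W <- matrix(0, nrow = 1L, ncol = k)
  W[1L, k] <- 1                     # pass through the target (last) frame
  model$blocks[[1]]$W <- W
  model$blocks[[1]]$b <- 0
  model$trained <- TRUE
  model$history <- 0
  model$norm_stats <- list(predictor = stats, target = stats)
  model
}

# minimal WFDB writer (format 16) used only to create reader fixtures
write_wfdb_fixture_16 <- function(dir, name, channels, fs = 360,
                                  gain = 200, baseline = 0) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  n <- length(channels[[1]])
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  lines <- sprintf("%s %d %g %d", name, length(channels), fs, n)
  for (i in seq_along(channels)) {
    lines <- c(lines, sprintf("%s 16 %g(%d)/mV 16 0 0 0 0 ch%d",
                              dat, gain, baseline, i))
  }
  writeLines(lines, hea)
  raw <- integer(n * length(channels))
  for (i in seq_along(channels)) {
    raw[seq(i, by = length(channels), length.out = n)] <-
      as.integer(round(channels[[i]] * gain + baseline))
  }
  writeBin(raw, file.path(dir, dat), size = 2L, endian = "little")
  file.path(dir, name)
}

# minimal WFDB writer (format 212), two channels interleaved
write_wfdb_fixture_212 <- function(dir, name, ch1, ch2, fs = 360,
                                   gain = 200) {
  stopifnot(length(ch1) == length(ch2))
  n <- length(ch1)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  writeLines(c(sprintf("%s 2 %g %d", name, fs, n),
               sprintf("%s 212 %g/mV 12 0 0 0 0 ch1", dat, gain),
               sprintf("%s 212 %g/mV 12 0 0 0 0 ch2", dat, gain)),
             hea)
  a <- as.integer(round(ch1 * gain)); b <- as.integer(round(ch2 * gain))
  to12 <- function(v) ifelse(v < 0L, v + 4096L, v)   # two's complement
  a <- to12(pmax(pmin(a, 2047L), -2048L))
  b <- to12(pmax(pmin(b, 2047L), -2048L))
  bytes <- raw(3L * n)
  for (i in seq_len(n)) {
    s1 <- a[i]; s2 <- b[i]
    bytes[3L * i - 2L] <- as.raw(bitwAnd(s1, 255L))
    bytes[3L * i - 1L] <- as.raw(bitwOr(bitwShiftR(s1, 8L),
                                        bitwShiftL(bitwShiftR(s2, 8L), 4L)))
    bytes[3L * i] <- as.raw(bitwAnd(s2, 255L))
  }
  writeBin(bytes, file.path(dir, dat))
  file.path(dir, name)
}

run_cli <- function(...) {
  script <- system.file("exec", "ecgdenoise.R", package = "rcedecg")
  if (!nzchar(script)) script <- file.path(find.package("rcedecg"), "exec", "ecgdenoise.R")
  rscript <- file.path(R.home("bin"), "Rscript")
  # nonzero exit is a legitimate outcome under test; the status attribute
  # carries it without a warning
  suppressWarnings(system2(rscript, c(script, ...), stdout = TRUE,
                           stderr = TRUE))
}
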