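# Colored-noise and motion-artifact corruption models with exact SNR
# calibration. Colored noise is synthesized by FFT-domain spectral shaping of
# white Gaussian noise, |H(f)| = f^(alpha/2) with the DC bin forced to zero,
# which gives the exact asymptotic power-law slope without filter transients.

noise_color_alpha <- c(white = 0, pink = -1, brown = -2, blue = 1, purple = 2)

#' Specification of a colored-noise corruption
#'
#' The five canonical colors map to power spectral densities proportional to
#' f^alpha: white (0), pink (-1), brown (-2), blue (+1), purple (+2).
#'
#' @param color one of `"white"`, `"pink"`, `"brown"`, `"blue"`, `"purple"`.
#' @param target_snr_db target signal-to-noise ratio in dB after scaling the
#'   noise against a clean reference.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(color, target_snr_db = -5) {
  if (!is.character(color) || length(color) != 1L ||
      !color %in% names(noise_color_alpha)) {
    stop("`color` must be one of: ",
         paste(names(noise_color_alpha), collapse = ", "), call. = FALSE)
  }
  stopifnot_scalar(target_snr_db, "target_snr_db")
  structure(
    list(color = color,
         spectral_exponent_alpha = unname(noise_color_alpha[color]),
         target_snr_db = target_snr_db),
    class = "noise_spec"
  )
}

#' Generate colored noise with PSD proportional to f^alpha
#'
#' White Gaussian noise is transformed to the frequency domain, each bin is
#' scaled by f^(alpha/2) (DC forced to zero), and the result is transformed
#' back. The output is exactly zero-mean and deterministic per seed.
#'
#' @param spec a [noise_spec()] (its `target_snr_db` is ignored here; see
#'   [scale_noise_to_snr()]).
#' @param n_samples number of samples (> 0).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return numeric vector of length `n_samples` with unit-order variance.
#' @export
generate_colored_noise <- function(spec, n_samples, fs, seed = 1L) {
  if (!inherits(spec, "noise_spec")) {
    stop("`spec` must be created by noise_spec()", call. = FALSE)
  }
  stopifnot_scalar(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  n <- as.integer(n_samples)
  alpha <- spec$spectral_exponent_alpha
  with_seed(seed, {
    w <- stats::rnorm(n)
    X <- stats::fft(w)
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) * fs / n        # two-sided frequency magnitude
    h <- numeric(n)
    nz <- f > 0
    h[nz] <- f[nz]^(alpha / 2)
    Y <- X * h                          # DC bin (f = 0) forced to zero
    y <- Re(stats::fft(Y, inverse = TRUE)) / n
    y <- y - mean(y)
    sd_y <- stats::sd(y)
    if (sd_y > 0) y <- y / sd_y         # unit variance before SNR scaling
    y
  })
}

#' Scale a noise series so the clean + noise mixture hits a target SNR
#'
#' The scale is the closed form sqrt(P_clean / (P_noise * 10^(target/10)))
#' with power the mean of squared samples, so the achieved SNR equals the
#' target to within floating-point rounding.
#'
#' @param clean clean reference series (nonzero power).
#' @param noise noise series of the same length (nonzero power).
#' @param target_snr_db target SNR in dB.
#' @return a list of class `corruption_result` with `clean`, `noise` (scaled),
#'   `noisy = clean + noise`, and `achieved_snr_db`.
#' @export
scale_noise_to_snr <- function(clean, noise, target_snr_db) {
  clean <- as.numeric(clean); noise <- as.numeric(noise)
  if (length(clean) != length(noise)) {
    stop("`clean` and `noise` must have equal length", call. = FALSE)
  }
  stopifnot_scalar(target_snr_db, "target_snr_db")
  p_clean <- signal_power(clean)
  p_noise <- signal_power(noise)
  if (p_clean == 0) stop("`clean` has zero power", call. = FALSE)
  if (p_noise == 0) stop("`noise` has zero power", call. = FALSE)
  scale <- sqrt(p_clean / (p_noise * 10^(target_snr_db / 10)))
  noisy <- clean + noise * scale
  # store the noise as the rounded difference so noisy - clean reproduces it
  # bit-exactly under IEEE arithmetic
  scaled <- noisy - clean
  structure(
    list(clean = clean, noise = scaled, noisy = noisy,
         achieved_snr_db = measure_snr(clean, noisy)),
    class = "corruption_result"
  )
}

#' Measure SNR of a corrupted series against a clean reference
#'
#' SNR = 10 log10(P_reference / P_residual) with the residual taken as
#' `corrupted - reference` and power the mean of squared samples. A corrupted
#' series identical to the reference returns `Inf` (zero residual), by
#' definition rather than as an error.
#'
#' @param reference clean reference series (nonzero power).
#' @param corrupted corrupted series of the same length.
#' @return SNR in dB (possibly `Inf`).
#' @export
measure_snr <- function(reference, corrupted) {
  reference <- as.numeric(reference); corrupted <- as.numeric(corrupted)
  if (length(reference) != length(corrupted)) {
    stop("`reference` and `corrupted` must have equal length", call. = FALSE)
  }
  p_ref <- signal_power(reference)
  if (p_ref == 0) stop("`reference` has zero power", call. = FALSE)
  p_res <- signal_power(corrupted - reference)
  if (p_res == 0) return(Inf)
  10 * log10(p_ref / p_res)
}

#' Specification of the motion-artifact surrogate
#'
#' Emulates arm-worn dry-electrode motion contamination as the sum of three
#' processes: low-frequency baseline wander (sinusoid plus random walk),
#' EMG-like band-limited noise bursts, and occasional step discontinuities
#' ("electrode pops").
#'
#' @param wander_amp_mv baseline wander amplitude (mV).
#' @param wander_freq_hz baseline wander center frequency (Hz).
#' @param burst_rate_per_s expected EMG burst rate (events/s).
#' @param burst_amp_mv burst envelope amplitude (mV, applied to unit-RMS
#'   band-limited noise).
#' @param burst_band_hz length-2 band of the burst carrier noise (Hz).
#' @param pop_prob_per_s expected electrode-pop rate (events/s).
#' @param pop_amp_mv pop step amplitude (mV).
#' @return an object of class `motion_artifact_spec`.
#' @export
motion_artifact_spec <- function(wander_amp_mv = 0.8,
                                 wander_freq_hz = 0.33,
                                 burst_rate_per_s = 2,
                                 burst_amp_mv = 8,
                                 burst_band_hz = c(20, 60),
                                 pop_prob_per_s = 0.5,
                                 pop_amp_mv = 4) {
  for (nm in c("wander_amp_mv", "burst_rate_per_s", "burst_amp_mv",
               "pop_prob_per_s", "pop_amp_mv")) {
    v <- get(nm)
    stopifnot_scalar(v, nm)
    if (v < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  stopifnot_scalar(wander_freq_hz, "wander_freq_hz", positive = TRUE)
  if (length(burst_band_hz) != 2L || burst_band_hz[1] <= 0 ||
      burst_band_hz[1] >= burst_band_hz[2]) {
    stop("`burst_band_hz` must be an increasing positive pair", call. = FALSE)
  }
  structure(
    list(wander_amp_mv = wander_amp_mv, wander_freq_hz = wander_freq_hz,
         burst_rate_per_s = burst_rate_per_s, burst_amp_mv = burst_amp_mv,
         burst_band_hz = burst_band_hz, pop_prob_per_s = pop_prob_per_s,
         pop_amp_mv = pop_amp_mv),
    class = "motion_artifact_spec"
  )
}

#' Generate a motion-artifact series
#'
#' @param spec a [motion_artifact_spec()].
#' @param n_samples number of samples (> 0).
#' @param fs sampling rate in Hz; the burst band must lie below `fs / 2`.
#' @param seed integer seed.
#' @return numeric artifact series (mV), deterministic per seed.
#' @export
generate_motion_artifact <- function(spec, n_samples, fs, seed = 1L) {
  if (!inherits(spec, "motion_artifact_spec")) {
    stop("`spec` must be created by motion_artifact_spec()", call. = FALSE)
  }
  stopifnot_scalar(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (spec$burst_band_hz[2] >= fs / 2) {
    stop("`burst_band_hz` must lie below fs / 2", call. = FALSE)
  }
  n <- as.integer(n_samples)
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    out <- numeric(n)
    # --- baseline wander: sinusoid with random phase + scaled random walk
    if (spec$wander_amp_mv > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      wander <- sin(2 * pi * spec$wander_freq_hz * t + phase)
      walk <- cumsum(stats::rnorm(n))
      walk <- walk - mean(walk)
      sdw <- stats::sd(walk)
      if (sdw > 0) walk <- walk / sdw
      out <- out + spec$wander_amp_mv * (wander + 0.5 * walk)
    }
    # --- EMG-like bursts: band-limited unit-RMS noise gated by half-sine
    #     envelopes at Poisson event times
    n_bursts <- stats::rpois(1, spec$burst_rate_per_s * n / fs)
    if (spec$burst_amp_mv > 0 && n_bursts > 0) {
      carrier <- fft_bandpass_noise(n, fs, spec$burst_band_hz)
      env <- numeric(n)
      starts <- sort(stats::runif(n_bursts, 0, n / fs))
      for (s in starts) {
        dur <- stats::runif(1, 0.1, 0.5)
        i0 <- floor(s * fs) + 1L
        i1 <- min(n, i0 + round(dur * fs) - 1L)
        if (i0 > n) next
        m <- i1 - i0 + 1L
        env[i0:i1] <- pmax(env[i0:i1], sin(pi * (seq_len(m) - 0.5) / m))
      }
      out <- out + spec$burst_amp_mv * carrier * env
    }
    # --- electrode pops: signed step discontinuities
    n_pops <- stats::rpois(1, spec$pop_prob_per_s * n / fs)
    if (spec$pop_amp_mv > 0 && n_pops > 0) {
      at <- sample.int(n, min(n_pops, n))
      for (i in at) {
        out[i:n] <- out[i:n] + sample(c(-1, 1), 1) * spec$pop_amp_mv
      }
    }
    out
  })
}

# White Gaussian noise band-limited by an ideal FFT mask, scaled to unit RMS.
fft_bandpass_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  rms <- sqrt(mean(y^2))
  if (rms > 0) y <- y / rms
  y
}
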