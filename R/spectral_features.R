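# Short-time Fourier analysis/synthesis and feature construction: 256-point
# Hamming STFT with 192-point overlap (hop 64), 129-bin one-sided magnitudes,
# sliding 8-frame context stacks, and per-bin train-time normalization.

#' STFT configuration
#'
#' Defaults match the denoising pipeline: 256-point frames, symmetric Hamming
#' window, 192-point (75%) overlap, so a real frame reduces to 129 one-sided
#' bins (`n_fft / 2 + 1`).
#'
#' @param n_fft frame length in samples.
#' @param overlap overlap between consecutive frames in samples (`0 <= overlap
#'   < n_fft`); the hop is `n_fft - overlap`.
#' @param fs sampling rate in Hz.
#' @return an object of class `stft_config` with derived fields `hop` and
#'   `n_bins`.
#' @export
stft_config <- function(n_fft = 256, overlap = 192, fs = 256) {
  stopifnot_scalar(n_fft, "n_fft", positive = TRUE)
  stopifnot_scalar(overlap, "overlap")
  stopifnot_scalar(fs, "fs", positive = TRUE)
  n_fft <- as.integer(n_fft); overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= n_fft) {
    stop("need 0 <= overlap < n_fft", call. = FALSE)
  }
  structure(
    list(n_fft = n_fft, overlap = overlap, hop = n_fft - overlap,
         n_bins = n_fft %/% 2L + 1L, fs = fs,
         window = hamming_window(n_fft)),
    class = "stft_config"
  )
}

n_stft_frames <- function(n, cfg) {
  if (n < cfg$n_fft) 0L else (n - cfg$n_fft) %/% cfg$hop + 1L
}

#' Short-time Fourier transform
#'
#' Windows the signal into Hamming-weighted frames (no padding; partial tail
#' samples are dropped) and keeps the one-sided spectrum, bins 0..n_fft/2.
#'
#' @param seq numeric series of length at least `cfg$n_fft`.
#' @param cfg an [stft_config()].
#' @return an object of class `spectrogram`: list with `frames` (complex
#'   matrix, n_frames x n_bins), `config`, and `origin_length`.
#' @export
stft <- function(seq, cfg = stft_config()) {
  seq <- as.numeric(seq)
  if (length(seq) < cfg$n_fft) {
    stop(sprintf("input too short for STFT: need >= %d samples, got %d",
                 cfg$n_fft, length(seq)), call. = FALSE)
  }
  nf <- n_stft_frames(length(seq), cfg)
  starts <- (seq_len(nf) - 1L) * cfg$hop
  # frame matrix: n_fft x n_frames, windowed, then column-wise FFT
  idx <- outer(seq_len(cfg$n_fft), starts, `+`)
  fr <- matrix(seq[idx], nrow = cfg$n_fft) * cfg$window
  sp <- stats::mvfft(fr)[seq_len(cfg$n_bins), , drop = FALSE]
  structure(
    list(frames = t(sp), config = cfg, origin_length = length(seq)),
    class = "spectrogram"
  )
}

#' Inverse STFT by weighted overlap-add
#'
#' Reconstructs the time series with least-squares synthesis: each one-sided
#' frame is expanded to a full spectrum, inverse-transformed, re-weighted by
#' the analysis window, overlap-added, and divided by the summed squared
#' window. On the fully-overlapped interior this inverts [stft()] to within
#' floating-point rounding; the first and last `n_fft` samples carry edge
#' attenuation (the evaluation protocol trims them).
#'
#' @param spec a `spectrogram`.
#' @param cfg an [stft_config()]; must match `spec$config`.
#' @return numeric series of length `spec$origin_length` (tail samples not
#'   covered by any frame are zero).
#' @export
istft <- function(spec, cfg = spec$config) {
  if (!inherits(spec, "spectrogram")) {
    stop("`spec` must be a spectrogram from stft()", call. = FALSE)
  }
  if (!identical(cfg$n_fft, spec$config$n_fft) ||
      !identical(cfg$hop, spec$config$hop)) {
    stop("`cfg` does not match the spectrogram's configuration", call. = FALSE)
  }
  nf <- nrow(spec$frames)
  n <- spec$origin_length
  half <- t(spec$frames)                           # n_bins x n_frames
  # rebuild the full conjugate-symmetric spectrum
  full <- matrix(0+0i, nrow = cfg$n_fft, ncol = nf)
  full[seq_len(cfg$n_bins), ] <- half
  if (cfg$n_fft > 2L) {
    full[(cfg$n_bins + 1L):cfg$n_fft, ] <-
      Conj(half[(cfg$n_bins - 1L):2L, , drop = FALSE])
  }
  fr <- Re(stats::mvfft(full, inverse = TRUE)) / cfg$n_fft
  y <- numeric(n)
  wsum <- numeric(n)
  w <- cfg$window
  for (j in seq_len(nf)) {
    at <- (j - 1L) * cfg$hop + seq_len(cfg$n_fft)
    y[at] <- y[at] + w * fr[, j]
    wsum[at] <- wsum[at] + w^2
  }
  nz <- wsum > 0
  y[nz] <- y[nz] / wsum[nz]
  y
}

#' Magnitude spectra of a spectrogram
#'
#' @param spec a `spectrogram`.
#' @return real matrix (n_frames x n_bins) of magnitudes.
#' @export
magnitudes <- function(spec) {
  if (!inherits(spec, "spectrogram")) stop("not a spectrogram", call. = FALSE)
  Mod(spec$frames)
}

#' Stack consecutive magnitude frames into network input contexts
#'
#' A sliding window (stride 1) of `k` consecutive frames. The network
#' predicts the frame at `target_index` of each stack; the default causal
#' convention predicts the last (most recent) frame.
#'
#' @param mags real matrix of magnitude frames (n_frames x n_bins).
#' @param k context length in frames (default 8).
#' @param target_index position (1-based) of the predicted frame within the
#'   context (default `k`).
#' @return an object of class `feature_stack`: list with `stacks` (array
#'   n_stacks x n_bins x k), `k`, `target_index`, and `target_frames` (the
#'   absolute frame index each stack predicts).
#' @export
stack_context <- function(mags, k = 8L, target_index = k) {
  mags <- as.matrix(mags)
  k <- as.integer(k); target_index <- as.integer(target_index)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (target_index < 1L || target_index > k) {
    stop("`target_index` must lie in [1, k]", call. = FALSE)
  }
  nf <- nrow(mags)
  if (nf < k) {
    stop(sprintf("need at least %d frames for a %d-frame context, got %d",
                 k, k, nf), call. = FALSE)
  }
  ns <- nf - k + 1L
  stacks <- array(0, dim = c(ns, ncol(mags), k))
  for (j in seq_len(k)) {
    stacks[, , j] <- mags[j:(j + ns - 1L), , drop = FALSE]
  }
  structure(
    list(stacks = stacks, k = k, target_index = target_index,
         target_frames = (seq_len(ns) - 1L) + target_index),
    class = "feature_stack"
  )
}

#' Fit per-bin normalization statistics
#'
#' Computes per-frequency-bin mean and standard deviation over a set of
#' magnitude frames, for zero-mean/unit-variance normalization. Standard
#' deviations are floored at `1e-8` so constant bins normalize to zero
#' rather than raising an error.
#'
#' @param mags real matrix (n_frames x n_bins) of training magnitudes, at
#'   least 2 frames.
#' @return an object of class `norm_stats` with `mean`, `sd` (both length
#'   n_bins) and `fitted = TRUE`.
#' @export
fit_normalizer <- function(mags) {
  mags <- as.matrix(mags)
  if (nrow(mags) < 2L) stop("need >= 2 frames to fit normalization", call. = FALSE)
  m <- colMeans(mags)
  # population (1/N) variance so that apply() yields unit variance exactly
  v <- colMeans(mags^2) - m^2
  s <- sqrt(pmax(v, 0))
  s <- pmax(s, 1e-8)
  structure(list(mean = m, sd = s, fitted = TRUE), class = "norm_stats")
}

#' Apply fitted normalization to magnitude data
#'
#' @param x matrix (frames x bins) or a `feature_stack` (normalized bin-wise
#'   across every context frame).
#' @param stats a `norm_stats` object from [fit_normalizer()].
#' @return object of the same shape with each bin centered and scaled by the
#'   training statistics.
#' @export
apply_norm <- function(x, stats) {
  check_norm_stats(stats)
  if (inherits(x, "feature_stack")) {
    out <- x
    nb <- dim(x$stacks)[2]
    for (j in seq_len(x$k)) {
      m <- matrix(x$stacks[, , j], ncol = nb)
      out$stacks[, , j] <- sweep(sweep(m, 2L, stats$mean), 2L, stats$sd, "/")
    }
    return(out)
  }
  x <- as.matrix(x)
  sweep(sweep(x, 2L, stats$mean), 2L, stats$sd, "/")
}

#' Invert fitted normalization
#'
#' @param x normalized matrix (frames x bins).
#' @param stats the `norm_stats` used to normalize.
#' @return matrix on the original magnitude scale.
#' @export
invert_norm <- function(x, stats) {
  check_norm_stats(stats)
  x <- as.matrix(x)
  sweep(sweep(x, 2L, stats$sd, "*"), 2L, stats$mean, "+")
}

check_norm_stats <- function(stats) {
  if (!inherits(stats, "norm_stats") || !isTRUE(stats$fitted)) {
    stop("`stats` must be fitted norm_stats from fit_normalizer()", call. = FALSE)
  }
  invisible(stats)
}
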