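# Signal conditioning chain for arm-worn ECG: resample to 256 Hz, zero-phase
# 3-25 Hz band-pass, 10-s segmentation, and edge trimming for evaluation.

#' Preprocessing configuration
#'
#' @param fs_target working sampling rate in Hz (default 256).
#' @param bp_low,bp_high band-pass cut-off frequencies in Hz (defaults 3 and
#'   25; the band keeps QRS energy and discards baseline wander and most
#'   muscle noise).
#' @param segment_s analysis segment duration in seconds (default 10).
#' @param edge_trim_s seconds trimmed from each end before evaluation
#'   (default 1, leaving the middle 8 s of a 10-s segment).
#' @param order Butterworth filter order (applied forward-backward, so the
#'   effective attenuation is doubled).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(fs_target = 256, bp_low = 3, bp_high = 25,
                              segment_s = 10, edge_trim_s = 1, order = 4) {
  stopifnot_scalar(fs_target, "fs_target", positive = TRUE)
  stopifnot_scalar(bp_low, "bp_low", positive = TRUE)
  stopifnot_scalar(bp_high, "bp_high", positive = TRUE)
  stopifnot_scalar(segment_s, "segment_s", positive = TRUE)
  stopifnot_scalar(edge_trim_s, "edge_trim_s")
  stopifnot_scalar(order, "order", positive = TRUE)
  if (!(bp_low < bp_high && bp_high < fs_target / 2)) {
    stop("need 0 < bp_low < bp_high < fs_target / 2", call. = FALSE)
  }
  if (edge_trim_s < 0 || 2 * edge_trim_s >= segment_s) {
    stop("need 0 <= 2 * edge_trim_s < segment_s", call. = FALSE)
  }
  structure(
    list(fs_target = fs_target, bp_low = bp_low, bp_high = bp_high,
         segment_s = segment_s, edge_trim_s = edge_trim_s, order = order),
    class = "preprocess_config"
  )
}

#' Resample a series between sampling rates
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling, which
#' is also the anti-alias filter) or zero-padded (upsampling) and inverse
#' transformed, so band-limited content below the lower Nyquist rate passes
#' with unit gain. The output length is
#' `round(length(seq) * fs_to / fs_from)`. Ringing from the implicit
#' periodic extension is confined to the sequence edges, which the
#' conditioning chain trims anyway.
#'
#' @param seq numeric series.
#' @param fs_from,fs_to source and target sampling rates in Hz.
#' @return resampled numeric series.
#' @export
resample_signal <- function(seq, fs_from, fs_to) {
  stopifnot_scalar(fs_from, "fs_from", positive = TRUE)
  stopifnot_scalar(fs_to, "fs_to", positive = TRUE)
  seq <- as.numeric(seq)
  if (length(seq) == 0L) return(numeric(0))
  if (fs_from == fs_to) return(seq)
  n <- length(seq)
  m <- as.integer(round(n * fs_to / fs_from))
  if (m == 0L) return(numeric(0))
  X <- stats::fft(seq)
  Y <- complex(m)
  keep <- min(n, m)
  nyq <- keep %/% 2L
  Y[1L] <- X[1L]
  if (nyq >= 1L) {
    Y[2L:(nyq + 1L)] <- X[2L:(nyq + 1L)]
    neg <- seq_len(nyq)
    Y[m - neg + 1L] <- X[n - neg + 1L]
  }
  # shared Nyquist bin of an even-length truncation: keep the result real
  if (keep %% 2L == 0L && nyq >= 1L) {
    if (m < n) {
      Y[nyq + 1L] <- X[nyq + 1L] + X[n - nyq + 1L]
    } else if (m > n) {
      Y[nyq + 1L] <- X[nyq + 1L] / 2
      Y[m - nyq + 1L] <- X[n - nyq + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`cfg$order` Butterworth band-pass (default 3-25 Hz)
#' forward and backward (`filtfilt`), so the output has no group delay and
#' R-peak annotations remain valid.
#'
#' @param seq numeric series.
#' @param fs sampling rate in Hz; must exceed `2 * cfg$bp_high`.
#' @param cfg a [preprocess_config()].
#' @return filtered series, same length as the input.
#' @export
bandpass <- function(seq, fs, cfg = preprocess_config()) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs <= 2 * cfg$bp_high) {
    stop("`fs` must exceed twice the upper cut-off", call. = FALSE)
  }
  seq <- as.numeric(seq)
  n <- length(seq)
  if (n == 0L) return(numeric(0))
  bf <- signal::butter(cfg$order, c(cfg$bp_low, cfg$bp_high) / (fs / 2),
                       type = "pass")
  # reflect the ends before forward-backward filtering so start-up
  # transients land in the padding, not in the output
  np <- min(n - 1L, as.integer(round(3 * fs / cfg$bp_low)))
  if (np > 0L) {
    padded <- c(2 * seq[1] - seq[(np + 1L):2L], seq,
                2 * seq[n] - seq[(n - 1L):(n - np)])
    out <- as.numeric(signal::filtfilt(bf, padded))
    out[(np + 1L):(np + n)]
  } else {
    as.numeric(signal::filtfilt(bf, seq))
  }
}

#' Split a series into consecutive non-overlapping segments
#'
#' Windows start at sample 1 and any trailing remainder shorter than a full
#' segment is dropped.
#'
#' @param seq numeric series.
#' @param fs sampling rate in Hz.
#' @param segment_s segment duration in seconds.
#' @return a list of numeric vectors, possibly empty.
#' @export
segment <- function(seq, fs, segment_s = 10) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(segment_s, "segment_s", positive = TRUE)
  seq <- as.numeric(seq)
  n_seg <- round(segment_s * fs)
  k <- length(seq) %/% n_seg
  lapply(seq_len(k), function(i) seq[((i - 1L) * n_seg + 1L):(i * n_seg)])
}

#' Trim evaluation edges from a segment
#'
#' Drops `edge_trim_s` seconds from each end (filter/transform edge effects),
#' e.g. the middle 8 s of a 10-s segment.
#'
#' @param seq numeric series of length at least `2 * edge_trim_s * fs`.
#' @param fs sampling rate in Hz.
#' @param edge_trim_s seconds to drop from each end.
#' @return the middle portion of `seq`.
#' @export
trim_edges <- function(seq, fs, edge_trim_s = 1) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(edge_trim_s, "edge_trim_s")
  if (edge_trim_s < 0) stop("`edge_trim_s` must be >= 0", call. = FALSE)
  seq <- as.numeric(seq)
  k <- round(edge_trim_s * fs)
  if (length(seq) < 2 * k) {
    stop(sprintf("series too short to trim %g s from each end (need >= %d samples, got %d)",
                 edge_trim_s, 2 * k, length(seq)), call. = FALSE)
  }
  if (k == 0L) return(seq)
  seq[(k + 1L):(length(seq) - k)]
}
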