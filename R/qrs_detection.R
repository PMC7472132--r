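# Pan-Tompkins QRS detection and tolerance-window peak matching.
#
# Classic pipeline: 5-15 Hz band-pass, five-point derivative, squaring,
# 150 ms moving-window integration, adaptive dual thresholds with running
# signal/noise level estimates, RR-based search-back, and T-wave
# discrimination. All filtering here is zero-phase and the integrator is
# centered, so detected indices align with R apexes without a group-delay
# correction.

#' Pan-Tompkins detector configuration
#'
#' @param pt_band length-2 band-pass for QRS enhancement in Hz (default
#'   5-15).
#' @param integration_window_s moving-window integration length in seconds
#'   (default 0.150).
#' @param refractory_s minimum spacing between accepted QRS events in
#'   seconds (default 0.200).
#' @param twave_window_s window after a QRS within which a candidate with
#'   less than half the preceding slope is rejected as a T wave (default
#'   0.360).
#' @param signal_update,noise_update exponential update coefficients of the
#'   running signal and noise peak estimates (defaults 0.125).
#' @param threshold_frac position of the detection threshold between the
#'   noise and signal estimates (default 0.25).
#' @param init_s seconds of integrated signal used to initialize the
#'   running estimates (default 2).
#' @return an object of class `peak_detection_config`.
#' @export
peak_detection_config <- function(pt_band = c(5, 15),
                                  integration_window_s = 0.150,
                                  refractory_s = 0.200,
                                  twave_window_s = 0.360,
                                  signal_update = 0.125,
                                  noise_update = 0.125,
                                  threshold_frac = 0.25,
                                  init_s = 2) {
  if (length(pt_band) != 2L || pt_band[1] <= 0 || pt_band[1] >= pt_band[2]) {
    stop("`pt_band` must be an increasing positive pair", call. = FALSE)
  }
  stopifnot_scalar(integration_window_s, "integration_window_s", positive = TRUE)
  stopifnot_scalar(refractory_s, "refractory_s", positive = TRUE)
  stopifnot_scalar(twave_window_s, "twave_window_s", positive = TRUE)
  if (refractory_s >= twave_window_s) {
    stop("`refractory_s` must be smaller than `twave_window_s`", call. = FALSE)
  }
  structure(
    list(pt_band = as.numeric(pt_band),
         integration_window_s = integration_window_s,
         refractory_s = refractory_s, twave_window_s = twave_window_s,
         signal_update = signal_update, noise_update = noise_update,
         threshold_frac = threshold_frac, init_s = init_s),
    class = "peak_detection_config"
  )
}

#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' @param seq numeric ECG series (any polarity; peak refinement uses the
#'   absolute amplitude of the input).
#' @param fs sampling rate in Hz (>= 100).
#' @param cfg a [peak_detection_config()].
#' @return strictly increasing integer vector of R-peak sample indices
#'   (1-based), spaced at least one refractory period apart.
#' @export
detect_rpeaks <- function(seq, fs, cfg = peak_detection_config()) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  seq <- as.numeric(seq)
  n <- length(seq)
  init_n <- round(cfg$init_s * fs)
  if (n < 2L * init_n) {
    stop(sprintf("series too short for detection: need >= %d samples, got %d",
                 2L * init_n, n), call. = FALSE)
  }
  if (all(seq == 0)) return(integer(0))
  # --- stage 1: band-pass (zero-phase), derivative, square, integrate
  bf <- signal::butter(3, cfg$pt_band / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, seq))
  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4]), recentered
  dkern <- c(2, 1, 0, -1, -2) / 8
  der <- stats::filter(filt, dkern, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  win <- max(1L, round(cfg$integration_window_s * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  mwi[is.na(mwi)] <- 0
  # --- stage 2: candidate peaks of the integrated signal
  cand <- local_maxima(mwi, min_dist = max(1L, round(cfg$refractory_s * fs / 2)))
  if (length(cand) == 0L) return(integer(0))
  # --- stage 3: adaptive dual thresholds with search-back
  spki <- 0.25 * max(mwi[seq_len(init_n)])
  npki <- 0.5 * mean(mwi[seq_len(init_n)])
  refr <- round(cfg$refractory_s * fs)
  twin <- round(cfg$twave_window_s * fs)
  qrs <- integer(0)
  qrs_slope <- numeric(0)
  rr_avg <- NA_real_
  noise_peaks <- integer(0)
  thr <- function() npki + cfg$threshold_frac * (spki - npki)
  slope_at <- function(i) {
    lo <- max(1L, i - round(0.075 * fs)); hi <- min(n, i + round(0.075 * fs))
    max(abs(der[lo:hi]), na.rm = TRUE)
  }
  accept <- function(i, searchback = FALSE) {
    co <- if (searchback) 0.25 else cfg$signal_update
    spki <<- co * mwi[i] + (1 - co) * spki
    qrs <<- c(qrs, i)
    qrs_slope <<- c(qrs_slope, slope_at(i))
    if (length(qrs) >= 2L) {
      rr <- diff(utils::tail(qrs, 9L))
      rr_avg <<- mean(rr)
    }
  }
  for (i in cand) {
    if (length(qrs) > 0L && i - qrs[length(qrs)] < refr) next
    is_sig <- mwi[i] > thr()
    if (is_sig && length(qrs) > 0L && i - qrs[length(qrs)] < twin) {
      # T-wave discrimination: reject if the slope collapsed
      if (slope_at(i) < 0.5 * qrs_slope[length(qrs_slope)]) is_sig <- FALSE
    }
    if (is_sig) {
      accept(i)
    } else {
      noise_peaks <- c(noise_peaks, i)
      npki <- cfg$noise_update * mwi[i] + (1 - cfg$noise_update) * npki
      # search-back: if the expected beat is overdue, take the best missed
      # candidate above half threshold
      if (length(qrs) > 0L && !is.na(rr_avg) &&
          i - qrs[length(qrs)] > 1.66 * rr_avg) {
        miss <- noise_peaks[noise_peaks > qrs[length(qrs)] + refr &
                              noise_peaks < i]
        miss <- miss[mwi[miss] > 0.5 * thr()]
        if (length(miss) > 0L) {
          accept(miss[which.max(mwi[miss])], searchback = TRUE)
          noise_peaks <- integer(0)
        }
      }
    }
  }
  if (length(qrs) == 0L) return(integer(0))
  # --- stage 4: refine each event to the R apex of the input waveform
  half <- as.integer(round(cfg$integration_window_s * fs / 2))
  peaks <- vapply(sort(qrs), function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    as.integer(lo + which.max(abs(seq[lo:hi])) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory contract after refinement
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) >= refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) >= refr)
    }
  }
  as.integer(peaks)
}

# indices of strict local maxima separated by at least min_dist samples
local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  is_max <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(is_max) <= 1L || min_dist <= 1L) return(is_max)
  # greedy suppression by height
  ord <- is_max[order(x[is_max], decreasing = TRUE)]
  taken <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Match detected peaks against reference annotations
#'
#' Greedy one-to-one nearest matching: candidate pairs within the tolerance
#' are accepted in order of increasing time difference, each reference and
#' each detected peak used at most once.
#'
#' @param reference sorted integer vector of reference R-peak indices.
#' @param detected sorted integer vector of detected R-peak indices.
#' @param fs sampling rate in Hz.
#' @param tolerance_ms matching tolerance in milliseconds (default 50).
#' @return an object of class `peak_match_result`: list with `tp`, `fp`,
#'   `fn`, `sensitivity_pct` (100 TP / (TP + FN)), `ppv_pct`
#'   (100 TP / (TP + FP); 0 with `ppv_defined = FALSE` when nothing was
#'   detected), and `tolerance_ms`.
#' @export
match_peaks <- function(reference, detected, fs, tolerance_ms = 50) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  reference <- as.integer(reference); detected <- as.integer(detected)
  if (is.unsorted(reference) || is.unsorted(detected)) {
    stop("`reference` and `detected` must be sorted", call. = FALSE)
  }
  tol <- tolerance_ms * fs / 1000
  tp <- 0L
  if (length(reference) > 0L && length(detected) > 0L) {
    d <- abs(outer(reference, detected, `-`))
    cand <- which(d <= tol, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_r <- logical(length(reference))
      used_d <- logical(length(detected))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_r[i] && !used_d[j]) {
          used_r[i] <- TRUE; used_d[j] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  fn <- length(reference) - tp
  fp <- length(detected) - tp
  sens <- if (length(reference) > 0L) 100 * tp / (tp + fn) else NA_real_
  ppv_defined <- length(detected) > 0L
  ppv <- if (ppv_defined) 100 * tp / (tp + fp) else 0
  structure(
    list(tp = tp, fp = fp, fn = fn, sensitivity_pct = sens, ppv_pct = ppv,
         ppv_defined = ppv_defined, tolerance_ms = tolerance_ms),
    class = "peak_match_result"
  )
}
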