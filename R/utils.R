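# Internal helpers shared across modules.

#' Evaluate an expression under a local random seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so package generators are deterministic without
#' clobbering user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Averaged-periodogram (Welch) power spectral density estimate
#'
#' Splits the signal into Hamming-windowed segments with 50% overlap,
#' averages their periodograms, and returns a one-sided PSD. Used by the
#' colored-noise slope checks and the ratio-of-power quality index.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param segment_s segment length in seconds (default 2).
#' @param overlap fractional overlap between consecutive segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz), DC bin included.
#' @export
welch_psd <- function(x, fs, segment_s = 2, overlap = 0.5) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  x <- as.numeric(x)
  nseg <- min(length(x), max(16L, round(segment_s * fs)))
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- hamming_window(nseg)
  u <- sum(w^2)                       # window power normalizer
  nb <- nseg %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    X <- stats::fft(seg)[seq_len(nb)]
    p <- Mod(X)^2 / (u * fs)
    # fold two-sided power into the one-sided estimate
    if (nseg %% 2L == 0L) {
      p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
    } else {
      p[2:nb] <- 2 * p[2:nb]
    }
    acc <- acc + p
  }
  list(freq = (seq_len(nb) - 1L) * fs / nseg, psd = acc / length(starts))
}

hamming_window <- function(n) {
  # symmetric (MATLAB-convention) Hamming window
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

signal_power <- function(x) mean(x^2)
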