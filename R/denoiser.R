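# End-to-end inference: noisy sequence -> STFT -> normalize with training
# statistics -> R-CED -> denormalize -> recombine with the noisy phase ->
# inverse STFT -> denoised sequence.

#' Denoise a sequence with a trained R-CED
#'
#' The noisy sequence is transformed with the training STFT configuration;
#' magnitude contexts are normalized with the predictor statistics fitted at
#' training time, passed through the network, denormalized with the target
#' statistics, clamped at zero, recombined with the noisy sequence's own
#' phase, and inverse-transformed. Frames not covered by a prediction (the
#' first `k - 1` frames of the causal context) keep the noisy magnitudes, so
#' the output has exactly the input length; the evaluation protocol trims
#' sequence edges anyway.
#'
#' @param model a trained `rced_model` carrying `norm_stats` (fitted
#'   predictor and target normalizers).
#' @param noisy numeric noisy sequence; must be long enough for at least one
#'   full context (`n_fft + (k - 1) * hop` samples).
#' @param cfg an [stft_config()]; must match the configuration used in
#'   training.
#' @return a list of class `denoise_result` with `denoised` (same length as
#'   `noisy`) and `n_clamped` (count of predicted magnitude bins clamped at
#'   zero after denormalization).
#' @export
denoise_sequence <- function(model, noisy, cfg = stft_config()) {
  if (!inherits(model, "rced_model") || !isTRUE(model$trained)) {
    stop("`model` must be a trained rced_model", call. = FALSE)
  }
  ns <- model$norm_stats
  if (is.null(ns) || is.null(ns$predictor) || is.null(ns$target)) {
    stop("`model` carries no normalization statistics; train with `norm_stats`",
         call. = FALSE)
  }
  noisy <- as.numeric(noisy)
  k <- model$config$context_k
  min_len <- cfg$n_fft + (k - 1L) * cfg$hop
  if (length(noisy) < min_len) {
    stop(sprintf("sequence too short to denoise: need >= %d samples, got %d",
                 min_len, length(noisy)), call. = FALSE)
  }
  sp <- stft(noisy, cfg)
  mag <- magnitudes(sp)
  phase <- Arg(sp$frames)
  st <- stack_context(mag, k = k, target_index = k)
  st_n <- apply_norm(st, ns$predictor)
  pred_n <- predict(model, st_n)
  pred <- invert_norm(pred_n, ns$target)
  n_clamped <- sum(pred < 0)
  pred[pred < 0] <- 0
  out_mag <- mag
  out_mag[st$target_frames, ] <- pred    # frames 1..k-1 keep noisy magnitudes
  sp_out <- sp
  sp_out$frames <- out_mag * exp(1i * phase)
  den <- istft(sp_out, cfg)
  # samples beyond the last full frame are not covered by the transform;
  # fall back to the noisy input there so the length contract holds
  covered <- (nrow(mag) - 1L) * cfg$hop + cfg$n_fft
  if (covered < length(noisy)) {
    den[(covered + 1L):length(noisy)] <- noisy[(covered + 1L):length(noisy)]
  }
  structure(list(denoised = den, n_clamped = n_clamped),
            class = "denoise_result")
}

#' Assemble a train-time dataset from clean/noisy sequence pairs
#'
#' Shared plumbing for training drivers: computes STFT magnitudes of every
#' pair, fits per-bin predictor (noisy) and target (clean) normalizers over
#' the pooled training frames, and returns aligned normalized contexts and
#' target frames.
#'
#' @param clean_list,noisy_list lists of equal-length numeric sequences.
#' @param cfg an [stft_config()].
#' @param k context length in frames.
#' @return list with `predictors` (array n x bins x k, normalized),
#'   `targets` (matrix n x bins, normalized) and `norm_stats`.
#' @export
build_training_set <- function(clean_list, noisy_list, cfg = stft_config(),
                               k = 8L) {
  if (length(clean_list) != length(noisy_list) || length(clean_list) == 0L) {
    stop("need matching non-empty lists of clean and noisy sequences",
         call. = FALSE)
  }
  noisy_mags <- lapply(noisy_list, function(x) magnitudes(stft(x, cfg)))
  clean_mags <- lapply(clean_list, function(x) magnitudes(stft(x, cfg)))
  stats_pred <- fit_normalizer(do.call(rbind, noisy_mags))
  stats_targ <- fit_normalizer(do.call(rbind, clean_mags))
  pred_list <- list(); targ_list <- list()
  for (i in seq_along(noisy_mags)) {
    st <- stack_context(noisy_mags[[i]], k = k, target_index = k)
    st_n <- apply_norm(st, stats_pred)
    pred_list[[i]] <- st_n$stacks
    targ_list[[i]] <- apply_norm(
      clean_mags[[i]][st$target_frames, , drop = FALSE], stats_targ)
  }
  n_bins <- dim(pred_list[[1]])[2]
  predictors <- array(0, dim = c(sum(vapply(pred_list, function(a) dim(a)[1], 0L)),
                                 n_bins, k))
  at <- 1L
  for (a in pred_list) {
    predictors[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  list(predictors = predictors,
       targets = do.call(rbind, targ_list),
       norm_stats = list(predictor = stats_pred, target = stats_targ))
}
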