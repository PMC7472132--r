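# Experiment drivers: the colored-noise corruption study and the
# motion-artifact study, plus the statistical tests used to compare
# conditions. The statistics are computed from first principles (sums of
# squares, distribution tails via pf/pt) so every number is auditable.

#' Experiment configuration
#'
#' Defaults mirror the study design: sixteen 10-s sequences per condition
#' split 10 train / 6 test for the colored-noise run; a 60/40 split of
#' clean/noisy pairs for the motion-artifact run (20 pairs by default, a
#' desk-scale stand-in for the original 69, configurable upward).
#'
#' @param n_train_sequences,n_test_sequences sequences per condition for the
#'   colored-noise experiment.
#' @param sequence_s sequence duration in seconds.
#' @param conditions data frame with columns `color` and `snr_db`; defaults
#'   to the full grid of five colors at two levels (-5/-7 dB, brown at
#'   -15/-17 dB, chosen so the noise amply buries the QRS complexes).
#' @param n_motion_pairs clean/noisy pair count for the motion experiment.
#' @param motion_train_frac fraction of motion pairs used for training
#'   (default 0.6).
#' @param pooled if `TRUE` (default) one network is trained on all
#'   colored-noise conditions pooled; otherwise one network per condition.
#' @param heart_rate_range heart-rate range (bpm) sampled per sequence.
#' @param seed master seed; all per-sequence seeds derive from it.
#' @param tc a [train_config()].
#' @param stft an [stft_config()].
#' @param pre a [preprocess_config()].
#' @param pt a [peak_detection_config()].
#' @param motion_spec a [motion_artifact_spec()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_train_sequences = 10L,
                              n_test_sequences = 6L,
                              sequence_s = 10,
                              conditions = default_noise_conditions(),
                              n_motion_pairs = 20L,
                              motion_train_frac = 0.6,
                              pooled = TRUE,
                              heart_rate_range = c(60, 100),
                              seed = 1L,
                              tc = train_config(),
                              stft = stft_config(),
                              pre = preprocess_config(),
                              pt = peak_detection_config(),
                              motion_spec = motion_artifact_spec()) {
  n_train_sequences <- as.integer(n_train_sequences)
  n_test_sequences <- as.integer(n_test_sequences)
  if (n_train_sequences < 1L || n_test_sequences < 1L) {
    stop("need at least one training and one test sequence", call. = FALSE)
  }
  if (!is.data.frame(conditions) || nrow(conditions) == 0L ||
      !all(c("color", "snr_db") %in% names(conditions))) {
    stop("`conditions` must be a non-empty data frame with color and snr_db",
         call. = FALSE)
  }
  if (motion_train_frac <= 0 || motion_train_frac >= 1) {
    stop("`motion_train_frac` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_train_sequences = n_train_sequences,
         n_test_sequences = n_test_sequences,
         sequence_s = sequence_s, conditions = conditions,
         n_motion_pairs = as.integer(n_motion_pairs),
         motion_train_frac = motion_train_frac, pooled = pooled,
         heart_rate_range = heart_rate_range, seed = as.integer(seed),
         tc = tc, stft = stft, pre = pre, pt = pt,
         motion_spec = motion_spec),
    class = "experiment_config"
  )
}

#' Default colored-noise condition grid
#'
#' Five colors at two SNR levels each: -5 and -7 dB for white, pink, blue
#' and purple; -15 and -17 dB for brown.
#'
#' @return data frame with columns `color` and `snr_db` (10 rows).
#' @export
default_noise_conditions <- function() {
  data.frame(
    color = rep(c("white", "blue", "pink", "purple", "brown"), each = 2L),
    snr_db = c(-5, -7, -5, -7, -5, -7, -5, -7, -15, -17),
    stringsAsFactors = FALSE
  )
}

# deterministic per-sequence sub-seed from the master seed (kept < 2^31)
derive_seed <- function(master, stream, index) {
  (as.integer(master) * 1009L + stream * 131L + index) %% 2147483647L
}

# generate one preprocessed clean sequence with annotations
make_clean_sequence <- function(cfg, stream, index) {
  sd <- derive_seed(cfg$seed, stream, index)
  bpm <- with_seed(sd + 7L, stats::runif(1, cfg$heart_rate_range[1],
                                         cfg$heart_rate_range[2]))
  rec <- generate_ecg(ecg_model_params(fs = cfg$pre$fs_target,
                                       heart_rate_bpm = bpm),
                      cfg$sequence_s, seed = sd)
  rec$samples <- bandpass(rec$samples, rec$fs, cfg$pre)
  rec
}

#' Run the colored-noise denoising experiment
#'
#' For every condition (noise color at a stated SNR), clean synthetic
#' sequences are corrupted with exactly calibrated colored noise; the R-CED
#' is trained on the training pairs (pooled across conditions by default)
#' and applied to held-out noisy sequences. Peak detection statistics and
#' quality indices are computed on the middle 8 s, together with the
#' repeated-measures ANOVA (ratio of power across clean/noisy/denoised) and
#' independent t-test (cross-correlation, noisy vs denoised).
#'
#' @param cfg an [experiment_config()].
#' @return an object of class `report_table`: a data frame with one row per
#'   condition.
#' @export
run_noise_experiment <- function(cfg = experiment_config()) {
  if (!inherits(cfg, "experiment_config")) {
    stop("`cfg` must be created by experiment_config()", call. = FALSE)
  }
  fs <- cfg$pre$fs_target
  n_tot <- cfg$n_train_sequences + cfg$n_test_sequences
  cleans <- lapply(seq_len(n_tot), function(i) make_clean_sequence(cfg, 1L, i))
  tr_idx <- seq_len(cfg$n_train_sequences)
  te_idx <- cfg$n_train_sequences + seq_len(cfg$n_test_sequences)
  # corrupt every sequence under every condition
  corrupt_one <- function(rec, cond_i, idx) {
    cond <- cfg$conditions[cond_i, ]
    noise <- generate_colored_noise(noise_spec(cond$color),
                                    length(rec$samples), fs,
                                    seed = derive_seed(cfg$seed, 100L + cond_i, idx))
    scale_noise_to_snr(rec$samples, noise, cond$snr_db)$noisy
  }
  train_model_on <- function(cond_set) {
    clean_list <- list(); noisy_list <- list()
    for (ci in cond_set) {
      for (i in tr_idx) {
        clean_list[[length(clean_list) + 1L]] <- cleans[[i]]$samples
        noisy_list[[length(noisy_list) + 1L]] <- corrupt_one(cleans[[i]], ci, i)
      }
    }
    ds <- build_training_set(clean_list, noisy_list, cfg$stft, k = 8L)
    model <- build_rced(rced_config(), seed = cfg$tc$seed)
    train_rced(model, ds$predictors, ds$targets, cfg$tc,
               norm_stats = ds$norm_stats)
  }
  pooled_model <- if (cfg$pooled) train_model_on(seq_len(nrow(cfg$conditions))) else NULL
  rows <- vector("list", nrow(cfg$conditions))
  for (ci in seq_len(nrow(cfg$conditions))) {
    model <- if (cfg$pooled) pooled_model else train_model_on(ci)
    per_seq <- lapply(te_idx, function(i) {
      clean <- cleans[[i]]$samples
      noisy <- corrupt_one(cleans[[i]], ci, i)
      den <- denoise_sequence(model, noisy, cfg$stft)$denoised
      evaluate_triplet(clean, noisy, den, cleans[[i]]$r_peaks, fs, cfg)
    })
    rows[[ci]] <- summarize_condition(per_seq,
                                      condition = sprintf("%s %g dB",
                                                          cfg$conditions$color[ci],
                                                          cfg$conditions$snr_db[ci]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("report_table", class(out))
  out
}

#' Run the motion-artifact denoising experiment
#'
#' Clean synthetic sequences are corrupted with the motion-artifact
#' surrogate (baseline wander, EMG-like bursts, electrode pops); both
#' channels pass the 3-25 Hz conditioning chain. The pairs are split
#' 60/40 into training and test sets; the trained network is evaluated on
#' the held-out noisy sequences.
#'
#' @param cfg an [experiment_config()].
#' @return a one-row `report_table`.
#' @export
run_motion_experiment <- function(cfg = experiment_config()) {
  if (!inherits(cfg, "experiment_config")) {
    stop("`cfg` must be created by experiment_config()", call. = FALSE)
  }
  if (cfg$n_motion_pairs < 4L) {
    stop("need at least 4 motion pairs", call. = FALSE)
  }
  fs <- cfg$pre$fs_target
  n <- cfg$n_motion_pairs
  n_train <- round(cfg$motion_train_frac * n)
  pairs <- lapply(seq_len(n), function(i) {
    sd <- derive_seed(cfg$seed, 2L, i)
    bpm <- with_seed(sd + 7L, stats::runif(1, cfg$heart_rate_range[1],
                                           cfg$heart_rate_range[2]))
    raw <- generate_ecg(ecg_model_params(fs = fs, heart_rate_bpm = bpm),
                        cfg$sequence_s, seed = sd)
    art <- generate_motion_artifact(cfg$motion_spec, length(raw$samples), fs,
                                    seed = sd + 13L)
    clean <- bandpass(raw$samples, fs, cfg$pre)
    noisy <- bandpass(raw$samples + art, fs, cfg$pre)
    list(clean = clean, noisy = noisy, r_peaks = raw$r_peaks)
  })
  ds <- build_training_set(lapply(pairs[seq_len(n_train)], `[[`, "clean"),
                           lapply(pairs[seq_len(n_train)], `[[`, "noisy"),
                           cfg$stft, k = 8L)
  model <- build_rced(rced_config(), seed = cfg$tc$seed)
  model <- train_rced(model, ds$predictors, ds$targets, cfg$tc,
                      norm_stats = ds$norm_stats)
  per_seq <- lapply(pairs[(n_train + 1L):n], function(p) {
    den <- denoise_sequence(model, p$noisy, cfg$stft)$denoised
    evaluate_triplet(p$clean, p$noisy, den, p$r_peaks, fs, cfg)
  })
  out <- summarize_condition(per_seq, condition = "motion artifact")
  out$n_train <- n_train
  out$n_test <- n - n_train
  class(out) <- c("report_table", class(out))
  out
}

# evaluate one clean/noisy/denoised triplet on the trimmed middle segment
evaluate_triplet <- function(clean, noisy, denoised, r_peaks, fs, cfg) {
  trim <- cfg$pre$edge_trim_s
  k <- round(trim * fs)
  ct <- trim_edges(clean, fs, trim)
  nt <- trim_edges(noisy, fs, trim)
  dt <- trim_edges(denoised, fs, trim)
  ref <- r_peaks[r_peaks > k & r_peaks <= length(clean) - k] - k
  in_window <- function(p) p[p >= 1L & p <= length(ct)]
  det <- list(
    clean = detect_rpeaks(clean, fs, cfg$pt) - k,
    noisy = detect_rpeaks(noisy, fs, cfg$pt) - k,
    denoised = detect_rpeaks(denoised, fs, cfg$pt) - k
  )
  mm <- lapply(det, function(p) match_peaks(ref, in_window(p), fs))
  list(sqi = sqi_report(ct, nt, dt, fs), match = mm)
}

summarize_condition <- function(per_seq, condition) {
  sq <- do.call(rbind, lapply(per_seq, function(x) as.data.frame(x$sqi)))
  agg_match <- function(which) {
    tp <- sum(vapply(per_seq, function(x) x$match[[which]]$tp, 0L))
    fn <- sum(vapply(per_seq, function(x) x$match[[which]]$fn, 0L))
    fp <- sum(vapply(per_seq, function(x) x$match[[which]]$fp, 0L))
    c(sens = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else 0)
  }
  mc <- agg_match("clean"); mn <- agg_match("noisy"); md <- agg_match("denoised")
  rop <- cbind(clean = sq$rop_clean, noisy = sq$rop_noisy,
               denoised = sq$rop_denoised)
  stats_rop <- if (nrow(rop) >= 3L) rm_anova_bonferroni(rop) else NULL
  p_xc <- if (nrow(sq) >= 2L) {
    independent_t_test(sq$xcorr_noisy, sq$xcorr_denoised)$p_value
  } else NA_real_
  data.frame(
    condition = condition,
    n_seq = nrow(sq),
    sens_clean = mc["sens"], ppv_clean = mc["ppv"],
    sens_noisy = mn["sens"], ppv_noisy = mn["ppv"],
    sens_denoised = md["sens"], ppv_denoised = md["ppv"],
    snr_imp_mean = mean(sq$snr_imp_db), snr_imp_sd = stats::sd(sq$snr_imp_db),
    rop_clean_mean = mean(sq$rop_clean), rop_clean_sd = stats::sd(sq$rop_clean),
    rop_noisy_mean = mean(sq$rop_noisy), rop_noisy_sd = stats::sd(sq$rop_noisy),
    rop_denoised_mean = mean(sq$rop_denoised),
    rop_denoised_sd = stats::sd(sq$rop_denoised),
    xcorr_noisy_mean = mean(sq$xcorr_noisy),
    xcorr_noisy_sd = stats::sd(sq$xcorr_noisy),
    xcorr_denoised_mean = mean(sq$xcorr_denoised),
    xcorr_denoised_sd = stats::sd(sq$xcorr_denoised),
    p_rop_noisy_vs_clean = if (is.null(stats_rop)) NA_real_ else
      stats_rop$pairwise["clean vs noisy", "p_adjusted"],
    p_rop_noisy_vs_denoised = if (is.null(stats_rop)) NA_real_ else
      stats_rop$pairwise["noisy vs denoised", "p_adjusted"],
    p_xcorr_noisy_vs_denoised = p_xc,
    row.names = NULL
  )
}

#' One-way repeated-measures ANOVA with Bonferroni post-hoc tests
#'
#' Computed from first principles: the total sum of squares is partitioned
#' into subject, condition, and residual components; the F statistic is
#' `MS_condition / MS_residual` with (k - 1) and (k - 1)(n - 1) degrees of
#' freedom. Post-hoc pairwise paired t-tests are Bonferroni-adjusted
#' (multiplied by the number of pairs, capped at 1).
#'
#' @param groups numeric matrix, one row per subject (sequence), one column
#'   per condition; balanced by construction. At least 3 subjects and 2
#'   conditions.
#' @return list with `F`, `df1`, `df2`, `p_value`, and `pairwise` (data
#'   frame of raw and adjusted p-values per condition pair).
#' @export
rm_anova_bonferroni <- function(groups) {
  groups <- as.matrix(groups)
  n <- nrow(groups); k <- ncol(groups)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(groups)) stop("unbalanced input: missing cells", call. = FALSE)
  grand <- mean(groups)
  ss_subj <- k * sum((rowMeans(groups) - grand)^2)
  ss_cond <- n * sum((colMeans(groups) - grand)^2)
  ss_tot <- sum((groups - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ss_cond <= .Machine$double.eps * max(1, ss_tot)) {
    f <- 0; p <- 1
  } else if (ms_err <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_cond / ms_err
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  cn <- colnames(groups)
  if (is.null(cn) || any(!nzchar(cn)) || anyDuplicated(cn)) {
    cn <- paste0("g", seq_len(k))
  }
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pw <- data.frame(pair = character(m), p_raw = numeric(m),
                   p_adjusted = numeric(m), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- groups[, pairs[1, j]]; b <- groups[, pairs[2, j]]
    pr <- paired_t_p(a, b)
    pw$pair[j] <- paste(cn[pairs[1, j]], "vs", cn[pairs[2, j]])
    pw$p_raw[j] <- pr
    pw$p_adjusted[j] <- min(1, pr * m)
  }
  rownames(pw) <- pw$pair
  list(F = f, df1 = df1, df2 = df2, p_value = p, pairwise = pw)
}

paired_t_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) return(if (mean(d) == 0) 1 else 0)
  tt <- mean(d) / (sd_d / sqrt(n))
  2 * stats::pt(abs(tt), n - 1L, lower.tail = FALSE)
}

#' Two-sample t-test computed from first principles
#'
#' Two-sided test on the difference of means; pooled-variance by default,
#' Welch's approximation optionally. Degenerate inputs (both samples
#' constant) return p = 1 when the means agree and p approaching 0
#' otherwise.
#'
#' @param a,b numeric samples of size >= 2.
#' @param welch if `TRUE`, use Welch's unequal-variance form.
#' @return list with `t`, `df`, and `p_value`.
#' @export
independent_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample must have size >= 2", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = na + nb - 2L, p_value = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2L,
                p_value = 0))
  }
  if (welch) {
    se2 <- va / na + vb / nb
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = tt, df = df, p_value = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
}
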