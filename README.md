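# rcedecg

Spectral-domain convolutional denoising of single-channel ECG, aimed at
recordings from arm-worn dry-electrode devices where motion artifacts and
muscle noise routinely bury the QRS complexes that heart-rate estimation
depends on.

The core method is a **redundant convolutional encoder–decoder (R-CED)**: a
fully convolutional network applied to short-time Fourier transform (STFT)
magnitude spectra. A noisy sequence x is conditioned to 256 Hz / 3–25 Hz,
transformed with a 256-point Hamming STFT (75% overlap, 129 one-sided
bins), and the network maps each sliding context of 8 consecutive
normalized magnitude frames to the corresponding clean frame:

    |S_clean(f, t)| ≈ g_θ( |S_noisy(f, t−7)| … |S_noisy(f, t)| )

g_θ is 16 blocks of 1-D convolution along frequency — blocks 1–15 followed
by batch normalization and ReLU, block 16 a bare convolution — with a
symmetric swell-and-shrink filter schedule and no pooling, trained by SGD
with momentum (batch 128, 12 epochs, learning rate ×0.95 per epoch) on
mean squared error of normalized magnitudes. The denoised magnitudes are
recombined with the noisy sequence's own phase and inverse-transformed by
weighted overlap-add. The conv-net, its backpropagation, and the training
loop are implemented in this package directly (im2col + BLAS); there is no
deep-learning framework dependency.

Evaluation follows the standard QRS-centric protocol: Pan–Tompkins R-peak
detection scored on the middle 8 s of each 10-s sequence with ±50 ms
tolerance, plus three signal quality indices — SNR improvement
(SNR_imp = SNR_denoised − SNR_noisy, both against the clean reference),
ratio of power in the 5–20 Hz band, and zero-lag cross-correlation with
the clean reference — compared across conditions with repeated-measures
ANOVA (Bonferroni post-hoc) and independent t-tests.

Everything runs on synthetic data with known ground truth: a
sum-of-Gaussians ECG generator with annotated R-peaks, five calibrated
colored noises (PSD ∝ f^α, α ∈ {0, −1, −2, +1, +2}, SNR exact to 1e−6 dB),
and a motion-artifact surrogate (baseline wander + EMG-like bursts +
electrode pops). A CSV record format and a minimal WFDB reader (formats 16
and 212) connect the pipeline to real recordings.

## Quick start

```r
library(rcedecg)

# a 10-s synthetic record with ground-truth R-peaks
rec <- generate_ecg(ecg_model_params(heart_rate_bpm = 72), duration_s = 10, seed = 1)
rec
#> <ecg_record> 2560 samples @ 256 Hz (10.00 s), 12 annotated R-peaks

# condition, then bury the QRS under white noise at exactly -5 dB
clean <- bandpass(rec$samples, fs = 256)
noise <- generate_colored_noise(noise_spec("white"), length(clean), fs = 256, seed = 2)
cor <- scale_noise_to_snr(clean, noise, target_snr_db = -5)
cor$achieved_snr_db
#> [1] -5

# detection collapses on the noisy channel
m_clean <- match_peaks(rec$r_peaks, detect_rpeaks(clean, 256), 256)
m_noisy <- match_peaks(rec$r_peaks, detect_rpeaks(cor$noisy, 256), 256)
c(m_clean$sensitivity_pct, m_noisy$sensitivity_pct)
#> [1] 100.0  66.7
c(ratio_of_power(clean, 256), ratio_of_power(cor$noisy, 256))
#> [1] 0.756 0.280
```

Training and applying the denoiser (a few minutes on one CPU):

```r
cfg <- experiment_config(conditions = data.frame(color = "white", snr_db = -5), seed = 1)
tab <- run_noise_experiment(cfg)   # 10 train / 6 test sequences, 12 epochs
tab[, c("sens_noisy", "sens_denoised", "snr_imp_mean",
        "rop_noisy_mean", "rop_denoised_mean",
        "xcorr_noisy_mean", "xcorr_denoised_mean")]
#>   sens_noisy sens_denoised snr_imp_mean rop_noisy_mean rop_denoised_mean
#> 1       78.5          93.8         6.81          0.254             0.566
#>   xcorr_noisy_mean xcorr_denoised_mean
#> 1            0.491               0.719
```

After denoising, detection sensitivity recovers from 78.5% to 93.8%, SNR
improves by ~7 dB, and both the QRS-band power fraction and the
correlation with the clean reference move most of the way back toward the
clean channel — the orderings the method is designed to produce.
`run_motion_experiment()` runs the analogous study against the
motion-artifact surrogate with a 60/40 train/test split.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript exec/ecgdenoise.R simulate --bpm 72 --duration 10 --seed 1 --fs 256 --out clean.csv
Rscript exec/ecgdenoise.R corrupt  --in clean.csv --color white --snr-db -5 --seed 2 --out noisy.csv
Rscript exec/ecgdenoise.R detect   --in noisy.csv --out peaks.txt
```

Subcommands: `simulate`, `corrupt`, `preprocess`, `train`, `denoise`,
`detect`, `score`, `evaluate`.

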