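---
title: "Spectral-domain convolutional denoising of wearable ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-domain convolutional denoising of wearable ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Arm-worn dry-electrode ECG devices sit over the biceps and triceps, so their
recordings are routinely contaminated by muscle activity, electrode motion,
and baseline wander. The clinical quantity of interest is usually not the
waveform itself but the R-peak train, from which heart rate and heart-rate
variability are derived; contamination that buries QRS complexes makes peak
detectors fire on noise or miss beats entirely.

`rcedecg` implements a denoising pipeline built around a redundant
convolutional encoder–decoder (R-CED): a fully convolutional network that
maps short-time Fourier transform (STFT) magnitude spectra of a noisy
sequence to the magnitude spectra of its clean counterpart. The denoised
magnitudes are recombined with the *noisy* sequence's own phase and
inverse-transformed. Because the network is convolutional along frequency
with no pooling, the spectral resolution is preserved end to end, and the
parameter count stays small enough for embedded use.

## Pipeline

1. **Conditioning** (`resample_signal`, `bandpass`, `segment`,
   `trim_edges`): signals are resampled to 256 Hz and band-passed to
   3–25 Hz, the band that retains QRS energy while discarding baseline
   wander and most electromyographic noise. Analysis operates on 10-s
   segments; the first and last second of each segment are excluded from
   every evaluation because both the zero-phase filters and the STFT have
   edge effects there.
2. **Spectral analysis** (`stft`, `stack_context`, `fit_normalizer`):
   256-point Hamming-window STFT with 192-point (75%) overlap, keeping the
   129 non-redundant bins of the one-sided spectrum. A 10-s segment yields
   37 frames. The network input is a sliding context of 8 consecutive
   normalized magnitude frames.
3. **Network** (`build_rced`, `train_rced`, `predict`): 16 convolutional
   blocks; blocks 1–15 are convolution + batch normalization + ReLU, block
   16 a bare convolution producing the single output frame. Trained with
   stochastic gradient descent with momentum, mini-batch 128, 12 epochs,
   learning rate multiplied by 0.95 after each epoch, minimizing mean
   squared error on normalized magnitudes.
4. **Synthesis** (`denoise_sequence`, `istft`): predictions are
   denormalized, clamped at zero, combined with the noisy phase, and
   inverse-transformed by least-squares weighted overlap-add.
5. **Evaluation** (`detect_rpeaks`, `match_peaks`, `sqi_report`,
   `run_noise_experiment`, `run_motion_experiment`): Pan–Tompkins R-peak
   detection scored against ground truth, plus three signal quality
   indices — SNR improvement, ratio of power in the 5–20 Hz band, and
   zero-lag cross-correlation with the clean reference — with
   repeated-measures ANOVA (Bonferroni post-hoc) and independent t-tests
   across conditions.

## The synthetic data and what it does (not) show

All experiments in this package run on synthetic ECG, standing in for the
clean channel of a multi-channel armband recording.

**Generator.** Each beat is a sum of five Gaussian deflections — P(−0.2 s,
0.15 mV, 0.025 s), Q(−0.03 s, −0.1 mV, 0.01 s), R(0, 1 mV, 0.012 s),
S(0.03 s, −0.15 mV, 0.01 s), T(0.25 s, 0.3 mV, 0.05 s) — placed on a beat
grid with i.i.d. Gaussian RR jitter (sd 20 ms, truncated at ±3 sd, RR
floored at 0.25 s). This is deliberately simpler than a limit-cycle
dynamical model: the downstream metrics depend only on R-peak timing and on
QRS energy lying inside the 3–25 Hz band, both of which the template
satisfies. The default rate is 256 Hz so records enter the pipeline after
the resampling stage; a 1000 Hz mode exercises the resampler.

**What passing tests show.** That the pipeline — calibration, transforms,
training dynamics, detection, statistics — behaves as designed, and that
the denoiser recovers QRS structure from corruptions it was trained on.
They do *not* show performance on real dry-electrode recordings:
real morphology varies beat to beat, arrhythmias and ectopy exist, motion
artifacts correlate with the ECG (both move with the arm), and the "clean"
reference channel of a real device is itself imperfect. The synthetic
corruption model is additive and independent by construction.

**Colored noise.** The five canonical colors (white, pink, brown, blue,
purple; PSD ∝ f^α with α = 0, −1, −2, +1, +2) are synthesized by FFT-domain
shaping of white Gaussian noise with |H(f)| = f^(α/2) and the DC bin forced
to zero. This gives the exact asymptotic slope with no filter transients.
Noise is scaled by the closed form `sqrt(P_clean / (P_noise ·
10^(SNR/10)))`, with power defined as the mean of squared samples, so the
achieved SNR equals the target to floating-point precision. Default levels
are −5/−7 dB (white, pink, blue, purple) and −15/−17 dB (brown), deep
enough to bury the QRS complexes. Brown noise needs far lower SNR because
almost all its power sits below the 3 Hz channel cutoff.

**Motion artifact surrogate.** Three additive processes: baseline wander
(sinusoid at 0.33 Hz plus a normalized random walk, 0.8 mV), EMG-like
bursts (20–60 Hz band-limited noise under half-sine envelopes, Poisson
arrivals), and electrode pops (signed step discontinuities, Poisson
arrivals). The burst and pop amplitudes (8 mV at 2/s; 4 mV at 0.5/s) are
calibrated so that, *after* the 3–25 Hz channel filter, Pan–Tompkins
sensitivity on the noisy channel falls to roughly 60% — the regime reported
for real motion-corrupted armband data. The amplitudes refer to the
wideband processes before channel filtering; since the 20–60 Hz carrier is
mostly above the 25 Hz cutoff, the wideband amplitude must be several times
the 1 mV R amplitude for its in-band residual to disrupt detection, which
is consistent with surface EMG on the upper arm dwarfing the arm-ECG
amplitude.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass | 3–25 | Hz | QRS band for arm ECG; removes wander and most EMG |
| filter | Butterworth order 4, forward–backward | — | zero phase keeps R-peak annotations valid |
| STFT | 256-pt Hamming, hop 64 | samples | 1-s frames at 256 Hz with 75% overlap; 129 one-sided bins |
| context | 8 frames, predict last | frames | causal context enables streaming use |
| filter schedule | 12,16,20,24,32,24,20,16,12,16,20,24,32,24,20,1 | channels | symmetric swell-and-shrink redundancy; last block 1 channel |
| kernel widths | 13,11,9,7,7,7,9,11,13,11,9,7,7,9,11,13 | bins | wider kernels at the ends, all odd for "same" padding |
| optimizer | SGDM, lr 0.01, momentum 0.9, decay 0.95/epoch | — | lr0/momentum are conventional; batch 128, 12 epochs |
| detector | 5–15 Hz, 150 ms integration, 200/360 ms rules | — | classic Pan–Tompkins constants, all exposed in config |
| matching tolerance | ±50 | ms | within half the integration window; standard in QRS benchmarking |

## Numerical and design choices

**One-sided 129-bin reduction.** "Reducing" a 256-point spectrum to 129
bins keeps the non-redundant half of a real signal's transform
(256/2 + 1); it is the only reduction consistent with lossless
reconstruction.

**iSTFT normalization.** A Hamming window at 75% overlap does not satisfy
the constant-overlap-add condition, so synthesis uses weighted overlap-add
with the least-squares normalizer (the running sum of squared analysis
windows). The round-trip is then exact (relative RMS error below 1e−10) on
the fully-overlapped interior; the outer `n_fft` samples carry edge
attenuation and are excluded by the 1-s evaluation trim.

**Normalization.** Per-frequency-bin mean and standard deviation (129 of
each) over all training frames, because spectral magnitudes span orders of
magnitude across bins; a single global pair would let low-frequency bins
dominate the loss. Predictors (noisy) and targets (clean) get separate
statistics; predictions are denormalized with the target statistics, then
clamped at zero since magnitudes are non-negative. Constant bins are
handled by flooring the standard deviation at 1e−8 rather than erroring.

**Context alignment.** The network predicts the last (most recent) frame of
its 8-frame context. The centered alternative is configurable; causal was
chosen because it permits streaming inference. The first 7 frames of a
sequence therefore have no prediction and fall back to the noisy
magnitudes — filled rather than zeroed so the output length equals the
input length without fabricating silence; the evaluation trim discards that
region anyway.

**Resampling.** Fourier-domain resampling (spectrum truncation or zero
padding) rather than polyphase filtering: truncation is itself the
anti-alias filter, passband gain is exactly 1, and the length contract
`round(n · fs_to/fs_from)` is met directly. Its edge ringing (from the
implicit periodic extension) is confined to the segment ends, which are
trimmed.

**Zero-phase filtering.** Forward–backward Butterworth filtering is applied
over reflection-padded input (three periods of the lowest passband
frequency) so start-up transients land in the padding. Without padding, a
DC step at the boundary leaks visible transient into the output.

**Batch normalization semantics.** Training uses batch statistics;
inference uses running averages (exponential update 0.1) frozen at
training time, so prediction is deterministic and independent of test batch
composition.

**Weight initialization.** Fan-in-scaled uniform, deterministic per seed.
Together with seeded shuffling this makes the entire training run
bit-reproducible on a single thread — a contract the test suite asserts.

**Detector ambiguity.** The headline "percent of correctly detected peaks"
in this literature is ambiguous between sensitivity and positive predictive
value. Both are computed and reported in every table; sensitivity is the
headline column. Matching is greedy one-to-one nearest-neighbor within
±50 ms.

**Statistics from first principles.** The repeated-measures ANOVA
(with Bonferroni-adjusted paired post-hoc t-tests) and the two-sample
t-test are computed from explicit sums of squares with distribution tails
from `pf`/`pt`, and are cross-checked in the test suite against
`stats::aov` and `stats::t.test` as independent implementations. The tests
are part of the reported pipeline, so they should be auditable rather than
hidden behind a formula interface.

**One model or ten.** The colored-noise experiment defaults to pooling all
conditions into one training set (100 sequences at the default scale) and
training a single network, with a per-condition mode behind a flag. The
per-condition tables are produced by evaluating that shared network on each
condition's held-out sequences.

## Experiment scale

The default experiment sizes are 10 training and 6 test sequences per
colored-noise condition and 20 motion pairs split 60/40 (12 train, 8
test) — the sequence counts of the original corruption design, with the
motion set scaled from 69 pairs to keep a full desk run in minutes; it is
configurable up to the original size. At this scale a single-condition
training run (300 contexts, 12 epochs, batch 128) takes a few minutes on
one CPU; detection, quality indices, and statistics are each a few seconds.

## Known limitations

- The beat model has fixed morphology per record: no ectopy, arrhythmia,
  respiration modulation, or electrode-position amplitude differences.
- The corruption model is additive and independent of the ECG; real motion
  artifacts are correlated with arm movement and non-stationary in ways the
  surrogate only caricatures.
- The network schedule is an engineering default; the original
  architecture's exact filter counts are not public, so parameter counts
  are not comparable.
- The WFDB reader supports single-file records in formats 16 and 212 only,
  and reads signals, not annotation files.
- `measure_snr` treats the residual against the reference as noise; for
  non-additive real data pairs this conflates morphology differences with
  noise.
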