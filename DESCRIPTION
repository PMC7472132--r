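Package: rcedecg
Title: Spectral-Domain Convolutional Denoising of Wearable ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoises single-channel electrocardiogram (ECG) recordings with a
    redundant convolutional encoder-decoder (R-CED) operating on short-time
    Fourier transform (STFT) magnitude spectra. Provides a synthetic ECG
    generator with ground-truth R-peak annotations, calibrated colored-noise
    and motion-artifact corruption models, the 3-25 Hz conditioning chain used
    for arm-worn dry-electrode devices, STFT analysis/synthesis with
    noisy-phase reconstruction, a from-scratch convolutional network trained
    by stochastic gradient descent with momentum, a Pan-Tompkins QRS detector,
    signal quality indices (SNR improvement, ratio of power in the 5-20 Hz
    band, cross-correlation against a clean reference), and experiment
    drivers with repeated-measures ANOVA and t-test statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
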