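Package: cardiosynth
Title: Coupled ECG-PPG Waveform Simulation, RR-Distribution Metrics, and
    Contrastive Adversarial PPG-to-ECG Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired electrocardiogram (ECG) and photoplethysmogram
    (PPG) signals from a coupled five-state ordinary differential equation
    model with per-cycle frequency modulation driven by an RR-interval
    schedule, for three rhythm morphologies (regular sinus rhythm, sinus
    arrhythmia, atrial fibrillation). Provides the accompanying signal
    conditioning chain (zero-phase bandpass filtering, anti-aliased
    resampling, first-peak alignment, overlapping fixed-window segmentation,
    min-max scaling), R-peak and RR-interval tools, a suite of RR-distribution
    and waveform comparison metrics (relative histogram intersection,
    relative RMSE, relative earth mover's distance, Kullback-Leibler
    divergence, Kolmogorov-Smirnov statistic, waveform RMSE, heart-rate MAE,
    Frechet distance), a contrastive-adversarial composite objective (NT-Xent
    contrastive loss, smooth-L1 reconstruction losses, vector-quantization
    losses, time- and frequency-domain adversarial losses), and a desk-scale
    dual-generator training and inference harness for PPG-to-ECG
    reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
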