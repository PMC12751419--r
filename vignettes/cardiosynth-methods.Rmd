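---
title: "Coupled ECG-PPG simulation and contrastive PPG-to-ECG reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled ECG-PPG simulation and contrastive PPG-to-ECG reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosynth)
```

## The problem

Photoplethysmography (PPG) is cheap and wearable; electrocardiography
(ECG) is the clinical reference for cardiac electrical activity. Because
every ventricular contraction produces both an electrical signature (the
QRS complex) and a pressure pulse (the PPG systolic peak), a long-standing
goal is to reconstruct the ECG waveform from the PPG alone. Two obstacles
dominate: paired training data are scarce and noisy, and models trained on
a handful of subjects do not transfer. `cardiosynth` addresses both at
desk scale: a mechanistic simulator that produces unlimited, perfectly
paired, morphology- and rhythm-controlled ECG/PPG records, and a
contrastive-adversarial translation model trained on windows of those
(or real) records.

## The oscillator

The simulator integrates a five-state system. A planar pair $(x, y)$ moves
on an attracting unit limit cycle with angular rate $\omega = 2\pi f$:

$$\dot x = \alpha x - \omega y, \qquad
  \dot y = \alpha y + \omega x, \qquad
  \alpha = 1 - \sqrt{x^2 + y^2}.$$

The ECG trace $z$ is pushed by one Gaussian bump per wave — five bumps
(P, Q, R, S, T) for regular sinus rhythm — anchored at phase angles
$\theta_i$ with amplitudes $a_i$ and angular widths $b_i$, and relaxed
towards a slow sinusoidal baseline $z_0(t) = A\sin(2\pi f_0 t)$:

$$\dot z = -\sum_i a_i\, \Delta\theta_i
  \exp\!\left(-\frac{\Delta\theta_i^2}{2 b_i^2}\right) - (z - z_0),
  \qquad \Delta\theta_i = \theta - \theta_i \;(\text{wrapped into }
  (-\pi, \pi]).$$

The PPG channel is driven by the squared ECG through an intermediary
state, which yields the characteristic smooth positive pulse that lags
the R peak:

$$\dot v = -B_0 v + B_1 w, \qquad \dot w = z^2 - B_2 w.$$

Defaults are $A = 0.01$, $f_0 = 0.25$, $B_0 = B_1 = 0.5$, $B_2 = 1.25$,
base frequency $\bar f = 0.1$, initial state
$u_0 = (1/\sqrt2,\, 1/\sqrt2,\, 0.2,\, 0.005,\, 0)$. Three rhythm presets
are built in: regular sinus rhythm (5 waves), sinus arrhythmia (7 waves,
erratic P activity) and atrial fibrillation (11 waves, fibrillatory P/T
activity); `rhythm_preset()` prints their full parameter vectors.

### Time scaling and RR-driven frequency modulation

One output sample advances ODE time by
$\mathrm{d}t = 1 / (\bar f \cdot \overline{RR})$, where $\overline{RR}$ is
the mean of the per-cycle RR schedule in samples. A cycle running at
$\bar f$ therefore spans exactly $\overline{RR}$ samples, and with
$\overline{RR}$ equal to the sampling rate one cycle lasts one second —
60 BPM. Cycle $c$ of the schedule runs at

$$f_c = \bar f \times \overline{RR} / RR_c,$$

so it spans exactly $RR_c$ samples. The schedule is how the simulator
emulates a real record: measure the PPG systolic peak-to-peak intervals
(`rr_schedule_from_ppg()`) and hand them to `simulate_pair()`.

**Where the frequency switches.** The angular rate is piecewise constant
and must change somewhere in the cycle. We switch it when the phase
crosses the R-peak angle $\theta = 0$. Switching anywhere else splits
each R-to-R interval across two frequencies, so the detected intervals
become moving averages of neighboring schedule entries — the emulated RR
distribution would be systematically narrowed (its standard deviation
shrunk by about $\sqrt2$) and unit-width histogram comparisons against
the driving schedule would degrade. Switching at the R peak makes every
R-to-R interval span exactly its scheduled number of samples; the
integration tests verify recovery to within one sample. The cost is a
slope discontinuity exactly at the R peak, which is negligible against
the R spike itself.

**Integrator.** Classical fixed-step 4th-order Runge-Kutta, one step per
output sample, in compiled code. A fixed step makes every simulation
bit-reproducible from `(preset, schedule, fs, seed, noise_frac)` alone;
an adaptive integrator would trade that determinism for accuracy the
application does not need (the orbit is smooth and the step is ~1/100 of
a cycle). Divergence (a non-finite state) raises an error rather than
returning garbage.

**Parameter noise.** Signal-pair diversity comes from perturbing every
waveform parameter once per record with zero-mean Gaussian noise whose
standard deviation is 10% of the parameter's magnitude. Widths are
clipped to stay positive; perturbed angles are wrapped but not re-sorted
(a swap of two nearby small waves is a legitimate morphology variant).
The R-peak anchor angle is 0 and therefore never moves, which keeps the
R-based timing contract intact.

## Preprocessing chain

For real recordings: zero-phase 4th-order Butterworth bandpass (ECG
0.4–45 Hz, PPG 0.3–8 Hz — chosen to keep QRS/T morphology on the ECG side
and cardiac/respiratory content on the PPG side), polyphase resampling to
125 Hz, first-peak alignment (crop so the first detected peaks of the two
channels coincide, absorbing the pulse-transit delay), per-record min-max
scaling to $[-1, 1]$, and segmentation into 512-sample windows with 50%
overlap (4.1 s at 125 Hz). Filtering is applied forward and backward so
peak positions do not shift — RR metrics downstream depend on that. The
filter family and order are not dictated by the data format; Butterworth-4
is the standard flat-passband choice. Mirror padding suppresses the
filtfilt edge transient. Scaling is per record, not per window, so
windows of one record remain mutually comparable; the incomplete final
window is dropped.

Simulator output is clean by construction, so the pipeline skips the
bandpass for synthetic records (`prepare_record(filter = FALSE)` is the
default).

## Metrics

RR-interval distributions are compared on shared unit-width (1 ms)
integer-edge histograms spanning the union support:

* **rHI** — histogram intersection over the smaller total count (1 =
  identical);
* **rEMD** — earth mover's distance $\sum_i |F_A(i) - F_B(i)|$ divided by
  its maximum `TotalEarth × MaxDistance`; the reference histogram A
  supplies TotalEarth and B is rescaled to equal mass. The tests verify
  this equals exhaustive optimal transport on all small instances;
* **KL** — divergence with $\varepsilon = 10^{-9}$ additive smoothing,
  natural log (asymmetric by design);
* **KS** — two-sample Kolmogorov-Smirnov statistic, evaluated exactly at
  the pooled sample points;
* **rRMSE** — RMSE between monotonically paired interval series (sorted;
  quantile interpolation when lengths differ) over the reference mean.
  The pairing convention matters because beat indices of two detectors
  need not correspond; monotone coupling is the canonical choice that
  makes rRMSE a pure distribution-shape comparison.

Waveform quality uses RMSE on the $[-1,1]$ scale, beat-wise heart-rate
MAE (HR = 60/RR s), HRV as mean and *population* standard deviation of
RR (with n in the denominator; at the 40–80 beats of a one-minute record
the distinction from the sample convention is below reporting precision),
and a Fréchet distance between Gaussian fits of per-window feature
clouds, $\|\mu_r - \mu_g\|^2 + \mathrm{Tr}(\Sigma_r + \Sigma_g -
2(\Sigma_r\Sigma_g)^{1/2})$, with the matrix square root via symmetric
eigendecomposition (negative eigenvalues clipped at zero). The feature
extractor is deliberately pluggable and deterministic; the default is the
flattened log-magnitude STFT of each window, and its identity is recorded
in every report.

## The reconstruction model

Training uses two generators and two discriminators. The PPG generator
$G_P$ autoencodes PPG windows; the ECG generator $G_E$ autoencodes ECG
windows; the cross path feeds the PPG latent into $G_E$'s decoder. After
training, inference uses only the encoder of $G_P$ and the decoder of
$G_E$ (the package asserts this by corrupting the unused halves in a
test). The objective is

$$L = \alpha L_{gen} + \beta L_t + \gamma L_f, \qquad
  (\alpha, \beta, \gamma) = (30, 3, 1),$$

where $L_{gen}$ sums an NT-Xent contrastive loss (temperature
$\tau = 0.1$) between the two encoders' latents — positives are the
time-aligned PPG/ECG windows of the same cardiac activity — and three
smooth-L1 reconstruction losses (PPG→PPG, ECG→ECG, PPG→ECG). $L_t$ and
$L_f$ are the standard GAN value functions of a time-domain discriminator
on ECG windows and a frequency-domain discriminator on one-sided STFT
magnitudes (128-point Hann, hop 32); the generator gradient is propagated
exactly through the magnitude STFT. The vector-quantized variant inserts
nearest-codebook quantization between encoder and decoder and adds the
dictionary and $\lambda$-weighted commitment terms ($\lambda = 0.25$)
with straight-through gradients.

Printed-formula readings we had to decide: NT-Xent is implemented with
$\tau$ inside the exponent (the standard definition the loss is named
after); the denominator includes the positive pair; logs are natural
throughout; smooth-L1 uses transition 1 and mean reduction; the
discriminator value function is used in its saturating form by default
(the non-saturating generator update is available as an option); the
contrastive term is PPG→ECG only, with no symmetric twin.

### Architecture

The generator internals are an engineering choice of this package. The
default is a compact 1-D convolutional encoder-decoder: a full-resolution
conv (kernel 9, 16 channels, tanh), one ×4 strided conv to 32 channels,
a dilation-4 conv at the quarter rate, and a 1×1 projection to an
8-channel latent map; the decoder mirrors this (1×1 expansion, dilated
conv, nearest ×4 upsampling, a kernel-5 refinement conv back to 16
channels) and its full-resolution level receives the encoder's
first-level features through an additive attention gate (per-channel
`relu`/`sigmoid` gating, coefficients exportable for inspection) before
a final kernel-9 conv and tanh output in $[-1,1]$. Two properties drove
this shape. Translation equivariance: beats occur anywhere in a window,
and a convolutional map generalizes across beat positions where a dense
map must memorize them (the package also ships the dense family, which
shows exactly this failure mode as a larger train/test gap). Temporal
precision and context: downsampling by more than ×4 makes sample-accurate
R-spike placement through the upsampling path practically unlearnable,
while the dilated trunk widens the receptive field to roughly ±1.5 beats
so the rhythm's regularity is visible to the cross-channel map.
Discriminators are small dense nets with sigmoid outputs. All forward/backward passes
are written explicitly in R with the convolution patch-gather in
compiled code; gradients are verified against finite differences in the
tests. Optimization is Adam (learning rate $10^{-3}$, betas 0.9/0.999),
batch size 32, alternating discriminator/generator updates; everything
is deterministic given the seed.

## The synthetic demo dataset

`make_demo_dataset()` writes n pairs per rhythm. Per pair it draws a
target RR mean uniformly from 600–900 ms (67–100 BPM, the resting range
the rhythm presets describe) and an RR standard deviation from 3–12 ms
(the short-term variability scale of resting recordings; the simulator's
own ground-truth HRV tables sit in this band), builds a Gaussian RR
schedule, truncated at ±3 SD, and applies one 10% parameter perturbation.
Records are one minute at 125 Hz by default, written with the first two
seconds dropped: the PPG state needs that long to settle from its initial
condition, and the settling bump is a simulator artifact, not physiology —
left in place it would capture the first-peak alignment. What this
emulates is
paired, beat-synchronous, morphologically plausible signals with
controllable rate and variability; what it does not emulate is motion
artifact, electrode noise, ectopy, or drift in the PPG-ECG coupling —
so green tests here demonstrate the method's correctness and its
behavior under ideal coupling, not clinical performance.

## Problem sizes used by the tests

The test suite runs everything fully synthetically: RR self-consistency
uses ten one-minute pairs per rhythm; the reconstruction check trains on
ten 40-second pairs per rhythm (two per rhythm held out) for 60 epochs —
a few minutes on one CPU. At that scale the harness recovers held-out
beat timing exactly (reconstructed R peaks within a sample) while
held-out waveform RMSE remains above the level that full-scale training
reaches: the limit is record diversity and model size, not the objective
— training at three times the pair count improves it markedly, and a
single record can be fit to RMSE well below 0.1. The sinus-arrhythmia
morphology is the hard case by design (its broad low-amplitude waves
stress both peak detection and reconstruction). One real-data comparison
(average RR-emulation fidelity over the 34 selected BIDMC records)
requires the PhysioNet download and therefore cannot run self-contained;
the machinery is exercised on synthetic stand-ins instead.

## Known limitations

* The PPG model is a two-state linear filter of $z^2$: it produces a
  plausible systolic pulse and exact beat timing, but no dicrotic notch,
  no amplitude-respiration coupling, and no site-dependent pulse shape.
* Peak detection is the plain distance-plus-prominence rule (minimum
  separation 50 samples, prominence ≥ 0.3 of the record range — chosen so
  preset T waves are rejected). On real, artifact-laden ECG a dedicated
  detector does better; any function with the same signature can be
  plugged into the evaluation path.
* The record-level min-max scaling is sensitive to a single extreme
  artifact sample in real data; filter first.
* Training is desk-scale by design. The architecture is deliberately
  small; nothing in the harness precludes swapping a deeper generator,
  but CPU time grows accordingly.
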