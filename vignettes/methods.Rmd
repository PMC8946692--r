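---
title: "Methods: multitaper spectrogram images and CNN sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitaper spectrogram images and CNN sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`somnostage` scores polysomnography (PSG) into the five AASM sleep stages
— Wake (W), N1, N2, N3 and REM (R), one label per 30-second epoch — from
two EEG and two EOG channels. The pipeline is:

1. **Preprocessing**: powerline notch (50 or 60 Hz), 0.3–35 Hz
   Butterworth band-pass, and linear-interpolation downsampling from
   250 Hz to 200 Hz where needed.
2. **Multitaper spectrograms**: per channel, DPSS tapers with
   time-half-bandwidth NW = 5 and K = 9 tapers, 5 s windows stepped by
   1 s, band-limited to 0–20 Hz.
3. **Epoch images**: each 30 s epoch yields a 30 × 103 time–frequency
   matrix per channel; the four channels tile into a 60 × 206 matrix,
   rendered in dB through a jet colormap to a 256 × 256 RGB raster and
   downscaled to a 64 × 64 × 3 input in [0, 1].
4. **Classification**: a CNN on the epoch images, or a CNN+LSTM on raw
   4 × 6000 epochs, trained with Adam, learning-rate annealing and early
   stopping.
5. **Evaluation**: accuracy, unweighted Cohen's kappa, 5 × 5 confusion
   matrices and hypnogram export.

A synthetic PSG generator with stage-dependent spectral content makes
the entire pipeline testable offline.

## Preprocessing

Both filters are applied forward–backward (`signal::filtfilt`), i.e.
zero-phase, so filtering never shifts epoch boundaries; the effective
magnitude response is the squared single-pass response. The notch is a
second-order IIR (RBJ cookbook) with Q = 30 — the quality factor is a
design choice: narrow enough to leave the 35 Hz-wide EEG band intact,
wide enough to remove realistic mains drift. The band-pass is a 4th-order
Butterworth; the order is the package's choice of standard PSG practice.
Filtering precedes resampling because the notch frequency is defined
relative to the native sampling rate.

Downsampling evaluates the signal at the 200 Hz time grid by linear
interpolation between native samples. No extra anti-alias filter is
used: the 35 Hz low-pass corner already bounds content far below the
100 Hz Nyquist frequency of the target rate. For a band-limited tone at
frequency f the linear-interpolation error is bounded by
(2&pi;f/f<sub>s</sub>)²/8, e.g. about 8 × 10⁻⁵ of the amplitude for a
1 Hz tone sampled at 250 Hz.

Re-applying the chain to data that were already filtered in acquisition
is harmless for in-band content: the passband is flat to within 0.5 dB,
so double filtering changes in-band amplitudes by at most that much.

## Multitaper spectrograms

DPSS tapers are computed by eigendecomposition of the standard symmetric
tridiagonal matrix that commutes with the concentration operator, then
ordered by their true spectral concentrations, evaluated as quadratic
forms with the dense sinc kernel. Tapers are unit-norm with a fixed sign
convention, so results are bit-reproducible.

Spectrogram conventions, fixed so that a 30 s epoch of a 200 Hz channel
yields exactly a 30 × 103 matrix:

* NFFT is the next power of two of the window sample count: 1024 for
  5 s at 200 Hz, giving a bin width of 200/1024 Hz; bins 0…102 cover
  0–19.92 Hz, and the band filter keeps `fmin ≤ f ≤ fmax` inclusive —
  103 bins for 0–20 Hz.
* Windows start at integer multiples of the 1 s step; a column belongs
  to the epoch containing its window start. The recording tail is
  reflection-padded by `window − step` = 4 s so a T-second recording
  yields exactly T columns and every epoch owns 30 of them.
* Each window is linearly detrended before tapering, which keeps
  within-window drift from leaking into the delta band.
* The K eigenspectra are averaged with equal weights (no adaptive
  weighting, no jackknifing), and the two-sided PSD is folded to one
  side in power-per-Hz units, so integrating the PSD over frequency
  recovers the window's mean power.
* The matrix is stored time-major: 30 time rows × 103 frequency columns.

## Epoch images

Power is displayed as 10·log₁₀(P + 10⁻¹²) dB. The display range is the
5th–95th percentile of dB values **per recording**, not per epoch:
per-epoch normalization would erase the absolute amplitude differences
(e.g. high-voltage delta) that distinguish N3. Values are clipped to the
range, mapped through a jet-like lookup table (the conventional display
for multitaper sleep spectrograms; monotone in each display channel the
way jet is), stretched anisotropically (aspect-ignoring bilinear,
because the target raster is square) to 256 × 256, and stored as 8-bit
RGB. The model input is a bilinear downscale to 64 × 64 divided by 255.
The colormap and normalization are defaults of this package — the
rendering convention upstream of the classifier is not standardized in
the field, so both are configurable and documented rather than claimed
canonical.

## Classifiers

**Spectrogram CNN** (input 64 × 64 × 3): three convolutional cells, each
`conv → batch norm → 2×2 max pool → Leaky ReLU`, with 64, 64 and 32
filters and 3 × 3 kernels (stride 1, same padding, so the spatial size
halves only at the pools: 64 → 32 → 16 → 8), then a dense head
1024 → dropout 0.25 → 512 → dropout 0.40 → 5 with softmax. Adam with
learning rate 0.002, batch size 16. 2,683,045 trainable parameters.

**Raw-signal CNN+LSTM** (input 6000 × 4): two 1D conv cells (80 filters,
kernel 3; then 32 filters, kernel 5; each with max-pool size 4, valid),
an LSTM with 10 units whose last output feeds dense 64 → dropout 0.45 →
dense 5 with softmax. After the two pools the sequence entering the LSTM
has ⌊⌊6000/4⌋/4⌋ = 375 steps. Adam with learning rate 0.001, batch
size 128.

Design points that were genuinely open:

* Batch normalization lives inside the conv cells only, following the
  definition of the convolutional cell; it is not inserted into the
  dense head.
* No activation is specified for the hidden dense layers; the package
  inserts the network's stated nonlinearity (Leaky ReLU) after the
  1024- and 512-unit layers (and the 64-unit layer of the CNN+LSTM),
  since without one the dense stack would collapse into a single linear
  map.
* The Leaky ReLU negative slope is 0.01 (the conventional default) and
  dropout rates are the layer-specific values 0.25/0.40 (CNN) and 0.45
  (CNN+LSTM).
* Weights are initialized Glorot-uniform, the default of the
  deep-learning frameworks this architecture family is normally built
  in.
* Ties in the output argmax resolve to the lowest stage index (W).
* No class weighting or oversampling is applied; N1 scarcity is a known
  limitation of epoch-level training, not corrected here.

The engine itself (im2col convolutions on BLAS, batch norm, max
pooling, LSTM, dropout, Adam) is implemented in R inside the package;
gradients of every layer are verified against numerical differentiation
in the test suite.

## Training schedule

20% of the training set is sampled once at the start of the run as the
validation set. After every epoch the validation loss feeds a plateau
detector: when the loss has not improved for `patience` epochs
(default 5; the value is the package's choice — any finite small value
works and it is configurable), the learning rate is divided by 5.
Training terminates when two successive decays occur with no improvement
between them, so the learning-rate trajectory is lr₀ → lr₀/5 → lr₀/25.
The parameters reported are those of the best validation-loss epoch.
All stochastic components — initialization, the validation split,
shuffling, dropout — derive from one run seed, so identical seed and
data reproduce identical epoch-wise losses. A `max_epochs` cap bounds
desk-scale runs.

## Synthetic data: what it emulates, and what it does not

The generator exists so the pipeline can be exercised and validated
without any external recording. A first-order Markov chain (default:
0.8 self-transition, remainder routed along plausible stage
adjacencies) produces the hypnogram; each epoch's 4-channel signal is
an independent 1/f Gaussian background (12 µV RMS) plus stage-specific
components with the canonical AASM signatures:

| stage | EEG | EOG |
|---|---|---|
| W  | 8–12 Hz alpha, 20 µV | — |
| N1 | 4–7 Hz theta, 15 µV | 0.2–0.6 Hz slow drifts, 40 µV |
| N2 | theta, 12 µV + 12–14 Hz spindle bursts (25 µV, ~5/min, 1 s) | — |
| N3 | 0.5–2 Hz delta, 75 µV | — |
| R  | low-amplitude theta, 8 µV | rapid biphasic deflections, antiphase on the two EOG channels (60 µV, ~20/min, 0.5 s) |

Spindles and REM deflections have Poisson onset times; REM deflections
are injected with opposite signs into EOG1 and EOG2, reproducing the
anticorrelation of conjugate eye movements on opposite-side electrodes.
An optional `eog_bleed` mixes eye-movement transients into the EEG
channels to mimic nose-reference artifacts (off by default). Amplitudes
were chosen once as typical adult scalp values; per-channel RMS stays
within 5–150 µV.

These signals are deliberately much cleaner than real PSG: stages are
exactly 30 s, stationary within epochs, with no artifacts, no
subject-to-subject variability, no arousals and no ambiguous
transitions. A nearest-centroid classifier on band powers already
exceeds 80% on them. Passing the end-to-end test therefore certifies
that the pipeline is wired correctly and that the network can learn
separable spectral structure — it says nothing about accuracy on real
recordings, which must be established on real data.

## Numerical choices and degenerate inputs

* dB floor ε = 10⁻¹² before the log; display range degenerates to a
  1 nV² span if the input is constant.
* `fs × window` and `fs × step` must be integers; recordings shorter
  than one window are rejected; trailing partial epochs are dropped with
  a warning.
* Epochs containing non-finite samples are dropped with a warning
  during preparation.
* Cohen's kappa of two identical constant sequences (chance agreement
  exactly 1) is defined as 1 and logged.
* Split sizes are ⌊n·f⌋ for validation and test with the remainder
  assigned to training.
* EDF encoding quantizes each channel over its own physical range into
  16 bits; round-trip error is bounded by range/65535.

## Problem sizes used in the bundled checks

The test suite runs entirely on synthetic data at desk scale, the
package's chosen sizes: the end-to-end learning check uses 5 × 200 =
1000 epochs (60/20/20 split) and a training budget of 6 epochs with
patience 2 — the annealing schedule's behaviour at full patience is
exercised separately on its own state machine. Metric properties use up
to 10,000 labels; Monte-Carlo spectral checks use 100–500 windows. The
separability reference uses 250 training and 500 held-out epochs.

## Known limitations

* Epoch-level random splits (no subject separation) match the original
  experimental design but overestimate generalization to new subjects;
  a by-subject split is available by preparing recordings separately.
* The ISRUC-style headline accuracies require the real public dataset
  and full-scale training; they are out of scope for the bundled tests.
* No EDF+ annotation parsing; stage labels come from plain text files.
* The raw-signal CNN+LSTM trains slowly on CPU at full batch size; it
  is validated functionally at reduced sizes.
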