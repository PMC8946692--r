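# somnostage

Automatic sleep-stage classification from multi-taper spectrogram
images of EEG/EOG.

## What this is

Scoring overnight polysomnography (PSG) into the five AASM stages —
Wake (W), N1, N2, N3 and REM (R), one label per 30-second epoch — is
the basis of sleep-disorder diagnostics, and doing it manually is slow
and inconsistent between scorers. `somnostage` implements an automatic
scorer for the minimal montage of two EEG and two EOG channels, aimed
at wearable-style recordings as much as standard PSG:

* **Signal I/O** — EDF and delimited-text recordings, plain-text
  hypnograms (AASM labels or ISRUC-style numeric codes), two-scorer
  consensus filtering.
* **Preprocessing** — 50/60 Hz notch, 0.3–35 Hz Butterworth band-pass
  (both zero-phase), linear-interpolation downsampling 250 → 200 Hz.
* **Multitaper spectrograms** — DPSS tapers (NW = 5, K = 9), 5 s
  windows stepped 1 s, 0–20 Hz band: each 30 s epoch of a 200 Hz
  channel becomes a 30 × 103 time–frequency matrix. The four channels
  tile into 60 × 206, render to a 256 × 256 RGB raster, and downscale
  to the 64 × 64 × 3 network input.
* **Classifiers** — a CNN on epoch images (conv cells 64/64/32 with
  batch norm, max-pooling and Leaky ReLU; dense 1024/512/5) and a
  CNN+LSTM on raw 6000 × 4 epochs (conv cells 80/32, LSTM 10 units,
  dense 64/5), trained with Adam, learning-rate annealing by a factor
  of 5 on validation plateaus, and early stopping after two successive
  decays. The neural-network engine (im2col convolutions over BLAS,
  batch norm, LSTM, Adam) is implemented in R in this package, and
  every layer's gradient is tested against numerical differentiation.
* **Evaluation** — accuracy, unweighted Cohen's kappa
  κ = (p₀ − pₑ)/(1 − pₑ), 5 × 5 confusion matrices (rows true, columns
  predicted, W…R order), hypnogram TSV + plot export.
* **Synthetic PSG** — a Markov-chain hypnogram plus stage-conditioned
  4-channel signal generator (alpha in W, theta in N1, spindles in N2,
  high-voltage delta in N3, antiphase rapid EOG deflections in R over a
  1/f background), so everything above is testable offline.

See `vignettes/methods.Rmd` for the model, conventions and their
rationale.

## Worked example

Generate a synthetic night, train the spectrogram CNN, and evaluate:

```r
library(somnostage)

set.seed(1)
h   <- hypnogram(sample(rep(0:4, each = 40)))          # 200 labeled epochs
rec <- synthesize_recording(h, synth_config(seed = 1))
rec <- preprocess_recording(rec)                        # notch + band-pass

imgs <- epoch_images(rec)$inputs                        # 64 x 64 x 3 x 200
sp   <- split_dataset(length(h), c(0.6, 0.2, 0.2), seed = 1)

fit <- fit_stagenet(imgs[, , , sp$train], h[sp$train], arch = "cnn",
                    schedule = train_schedule(patience = 2, max_epochs = 6),
                    seed = 1)
print(fit)
#> Sleep-stage classifier (cnn)
#>   trained on 120 epochs, seed 1
#>   6 training epochs, best val loss 0.0107 (val acc 1.000), 0 lr decay(s)

report <- evaluate_predictions(predict(fit, imgs[, , , sp$test]),
                               h[sp$test])
print(report)
#> <eval_report> n = 40 epochs | accuracy 95.00% | kappa 0.937
#>     predicted
#> true W N1 N2 N3  R
#>   W  6  0  0  0  0
#>   N1 0  5  0  0  0
#>   N2 0  2  8  0  0
#>   N3 0  0  0  8  0
#>   R  0  0  0  0 11
```

The accuracy is the fraction of the 40 held-out epochs scored
identically to the ground truth; kappa corrects that agreement for
chance given the stage marginals. The confusion matrix shows where the
remaining errors live (here two N2 epochs scored as N1). Synthetic data
are much cleaner than real PSG — see the vignette
for what this does and does not demonstrate.

The same pipeline runs from the shell via `inst/cli/somnostage`
(`synth`, `prepare`, `train`, `predict`, `evaluate` subcommands), with
EDF recordings, hypnogram text files and a YAML config.

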