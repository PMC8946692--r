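# Synthetic polysomnography with known stage structure: a first-order
# Markov hypnogram plus stage-conditioned 4-channel EEG/EOG synthesis
# (1/f background with stage-specific oscillations and transients), so
# the whole pipeline is exercisable without any external recording.

# default stage-transition matrix: strong self-transitions (hypnogram
# inertia) with sleep-like routing of the remainder
.default_transition <- function() {
  m <- matrix(c(
    0.80, 0.15, 0.02, 0.01, 0.02,   # from W
    0.05, 0.80, 0.12, 0.01, 0.02,   # from N1
    0.02, 0.05, 0.80, 0.09, 0.04,   # from N2
    0.01, 0.02, 0.12, 0.80, 0.05,   # from N3
    0.04, 0.06, 0.08, 0.02, 0.80),  # from R
    nrow = 5, byrow = TRUE,
    dimnames = list(stage_levels(), stage_levels()))
  m
}

# per-stage oscillation parameters: amplitudes in µV, bands in Hz,
# burst rates in events/min
.default_stage_params <- function() {
  list(
    W  = list(eeg_band = c(8, 12),  eeg_amp = 20, eog_amp = 0),
    N1 = list(eeg_band = c(4, 7),   eeg_amp = 15, eog_amp = 40,
              eog_band = c(0.2, 0.6)),
    N2 = list(eeg_band = c(4, 7),   eeg_amp = 12, eog_amp = 0,
              spindle_amp = 25, spindle_band = c(12, 14),
              spindle_rate = 5, spindle_dur = 1.0),
    N3 = list(eeg_band = c(0.5, 2), eeg_amp = 75, eog_amp = 0),
    R  = list(eeg_band = c(4, 7),   eeg_amp = 8,
              rem_amp = 60, rem_rate = 20, rem_dur = 0.5))
}

#' Synthetic-dataset configuration
#'
#' Defaults emulate the canonical AASM stage signatures: alpha (8-12 Hz)
#' in W, theta (4-7 Hz) with slow EOG drifts in N1, theta plus 12-14 Hz
#' spindle bursts in N2, high-amplitude 0.5-2 Hz delta in N3, and mixed
#' theta with rapid antiphase EOG deflections in R — all over a 1/f
#' Gaussian background of about 12 µV RMS per channel.
#'
#' @param n_epochs Number of 30 s epochs per recording.
#' @param fs Sampling rate, 200 or 250 Hz.
#' @param transition 5x5 stage-transition matrix (rows sum to 1).
#' @param stage_params Per-stage oscillation parameters; see the default
#'   for the structure.
#' @param noise_rms RMS of the 1/f background per channel, µV.
#' @param noise_exponent Spectral slope of the background (power ~
#'   1/f^exponent).
#' @param eog_bleed Fraction of the EOG transients mixed into the EEG
#'   channels (0 = off), mimicking nose-reference eye-movement artifacts.
#' @param seed Generator seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_epochs = 40, fs = 200,
                         transition = .default_transition(),
                         stage_params = .default_stage_params(),
                         noise_rms = 12, noise_exponent = 1,
                         eog_bleed = 0, seed = 1L) {
  if (!fs %in% c(200, 250)) stop("fs must be 200 or 250 Hz")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition-matrix rows must sum to 1")
  if (any(transition < 0)) stop("transition probabilities must be >= 0")
  structure(list(n_epochs = n_epochs, fs = fs, transition = transition,
                 stage_params = stage_params, noise_rms = noise_rms,
                 noise_exponent = noise_exponent, eog_bleed = eog_bleed,
                 seed = seed),
            class = "synth_config")
}

#' Simulate a hypnogram from the Markov stage model
#'
#' First-order Markov chain over the five stages, started at W.
#'
#' @param cfg A [synth_config()].
#' @param seed Optional seed override (defaults to `cfg$seed`).
#' @return A [hypnogram()] of length `cfg$n_epochs`.
#' @export
simulate_hypnogram <- function(cfg = synth_config(), seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed else seed)
  P <- cfg$transition
  s <- integer(cfg$n_epochs)
  cur <- 1L                                # W
  for (i in seq_len(cfg$n_epochs)) {
    s[i] <- cur - 1L
    cur <- sample.int(5L, 1L, prob = P[cur, ])
  }
  hypnogram(s)
}

# 1/f^a Gaussian noise of length n, unit RMS, via frequency-domain shaping
.pink_noise <- function(n, fs, exponent) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1)) * fs / n       # avoid DC singularity
  f <- pmin(f, fs - f + fs / n)            # mirror for the upper half
  shape <- 1 / f^(exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# narrowband oscillation: sinusoid with uniformly drawn frequency within
# the band and random phase; amp is the peak amplitude
.oscillation <- function(n, fs, band, amp) {
  f0 <- stats::runif(1, band[1], band[2])
  ph <- stats::runif(1, 0, 2 * pi)
  amp * sin(2 * pi * f0 * (seq_len(n) - 1) / fs + ph)
}

# Hann-windowed tone bursts at Poisson onsets; rate in events/min
.bursts <- function(n, fs, band, amp, rate, dur_s) {
  out <- numeric(n)
  n_ev <- stats::rpois(1, rate * n / fs / 60)
  if (n_ev == 0) return(out)
  len <- round(dur_s * fs)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
  for (e in seq_len(n_ev)) {
    start <- sample.int(max(1L, n - len), 1L)
    f0 <- stats::runif(1, band[1], band[2])
    tone <- amp * win * sin(2 * pi * f0 * seq_len(len) / fs +
                              stats::runif(1, 0, 2 * pi))
    idx <- start:(start + len - 1L)
    out[idx] <- out[idx] + tone
  }
  out
}

# biphasic eye-movement deflections (derivative-of-Gaussian pulses) at
# Poisson onsets; returns the waveform added to EOG1 and subtracted from
# EOG2 (antiphase, as the two electrodes sit on opposite sides)
.rem_deflections <- function(n, fs, amp, rate, dur_s) {
  out <- numeric(n)
  n_ev <- stats::rpois(1, rate * n / fs / 60)
  if (n_ev == 0) return(out)
  len <- round(dur_s * fs)
  t_ <- seq(-2.5, 2.5, length.out = len)
  pulse <- -t_ * exp(-t_^2 / 2)
  pulse <- amp * pulse / max(abs(pulse))
  for (e in seq_len(n_ev)) {
    start <- sample.int(max(1L, n - len), 1L)
    idx <- start:(start + len - 1L)
    out[idx] <- out[idx] + sample(c(-1, 1), 1) * pulse
  }
  out
}

#' Synthesize one stage-conditioned 4-channel segment
#'
#' Channels are EEG1, EEG2, EOG1, EOG2. Each carries an independent 1/f
#' background; the stage determines the added oscillations (see
#' [synth_config()]). During R the EOG deflections are injected in
#' antiphase (EOG1 up, EOG2 down), as rapid conjugate eye movements
#' appear on electrodes on opposite sides of the eyes.
#'
#' @param stage Stage code 0..4 or name.
#' @param duration_s Segment duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param cfg A [synth_config()].
#' @param seed Optional seed (set it for standalone reproducible calls;
#'   leave NULL inside a larger seeded simulation).
#' @return 4 x n matrix (µV), rows EEG1, EEG2, EOG1, EOG2.
#' @export
synthesize_stage_signal <- function(stage, duration_s, fs = 200,
                                    cfg = synth_config(fs = fs),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(stage)) stage <- as.integer(hypnogram(stage))
  if (!stage %in% 0:4) stop("unknown stage code: ", stage)
  sp <- cfg$stage_params[[stage + 1L]]
  n <- round(duration_s * fs)
  if (n < 1) stop("duration_s must be positive")

  ch <- matrix(0, 4, n)
  for (j in 1:4)
    ch[j, ] <- cfg$noise_rms * .pink_noise(n, fs, cfg$noise_exponent)

  for (j in 1:2)                                 # EEG oscillation
    ch[j, ] <- ch[j, ] + .oscillation(n, fs, sp$eeg_band, sp$eeg_amp)

  if (!is.null(sp$spindle_amp))                  # N2 spindle bursts
    for (j in 1:2)
      ch[j, ] <- ch[j, ] + .bursts(n, fs, sp$spindle_band, sp$spindle_amp,
                                   sp$spindle_rate, sp$spindle_dur)

  if (!is.null(sp$eog_amp) && sp$eog_amp > 0)    # N1 slow EOG drifts
    for (j in 3:4)
      ch[j, ] <- ch[j, ] + .oscillation(n, fs, sp$eog_band, sp$eog_amp)

  if (!is.null(sp$rem_amp)) {                    # R antiphase deflections
    defl <- .rem_deflections(n, fs, sp$rem_amp, sp$rem_rate, sp$rem_dur)
    ch[3, ] <- ch[3, ] + defl
    ch[4, ] <- ch[4, ] - defl
    if (cfg$eog_bleed > 0)
      for (j in 1:2) ch[j, ] <- ch[j, ] + cfg$eog_bleed * defl
  }
  rownames(ch) <- c("EEG1", "EEG2", "EOG1", "EOG2")
  ch
}

#' Synthesize a recording that realizes a given hypnogram
#'
#' @param h A [hypnogram()].
#' @param cfg A [synth_config()].
#' @param seed Optional seed override.
#' @return A [recording()] with channels EEG1, EEG2, EOG1, EOG2 at
#'   `cfg$fs`.
#' @export
synthesize_recording <- function(h, cfg = synth_config(), seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed else seed)
  segs <- lapply(as.integer(h), function(s)
    synthesize_stage_signal(s, 30, cfg$fs, cfg))
  recording(t(do.call(cbind, segs)),
            channels = c("EEG1", "EEG2", "EOG1", "EOG2"), fs = cfg$fs)
}

#' Generate a synthetic labeled dataset
#'
#' Each recording gets its own Markov hypnogram and matching signals;
#' recording r is seeded deterministically from `cfg$seed + r`.
#'
#' @param cfg A [synth_config()].
#' @param n_recordings Number of recordings.
#' @return List of `n_recordings` elements, each
#'   `list(recording, hypnogram)`.
#' @export
generate_dataset <- function(cfg = synth_config(), n_recordings = 1L) {
  lapply(seq_len(n_recordings), function(r) {
    h <- simulate_hypnogram(cfg, seed = cfg$seed + r)
    rec <- synthesize_recording(h, cfg, seed = cfg$seed + r)
    list(recording = rec, hypnogram = h)
  })
}

#' Stationary distribution of the stage-transition chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1,
#' normalized to sum to 1.
#'
#' @param transition 5x5 row-stochastic matrix.
#' @return Named numeric vector over W, N1, N2, N3, R.
#' @export
stationary_distribution <- function(transition = .default_transition()) {
  eg <- eigen(t(transition))
  v <- Re(eg$vectors[, which.min(abs(eg$values - 1))])
  v <- v / sum(v)
  names(v) <- stage_levels()
  v
}

#' Per-epoch spectral band powers
#'
#' Periodogram band powers (delta 0.5-4, theta 4-8, alpha 8-12, sigma
#' 12-15 Hz) per channel, the classical feature set that separates the
#' five stages; used by the nearest-centroid reference classifier.
#'
#' @param rec A 4-channel [recording()].
#' @return n_epochs x 16 matrix (4 bands x 4 channels), log10 power.
#' @export
band_power_features <- function(rec) {
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 12), sigma = c(12, 15))
  n_ep <- floor(rec$duration_s / 30)
  nseg <- 30 * rec$fs
  out <- matrix(0, n_ep, 16)
  for (e in seq_len(n_ep)) {
    rows <- ((e - 1) * nseg + 1):(e * nseg)
    for (j in 1:4) {
      x <- rec$data[rows, j]
      X <- stats::fft(x - mean(x))
      half <- floor(nseg / 2)
      psd <- Mod(X[seq_len(half)])^2 / (nseg * rec$fs)
      f <- (seq_len(half) - 1) * rec$fs / nseg
      for (b in seq_along(bands)) {
        sel <- f >= bands[[b]][1] & f < bands[[b]][2]
        out[e, (j - 1) * 4 + b] <- log10(sum(psd[sel]) * rec$fs / nseg + 1e-12)
      }
    }
  }
  colnames(out) <- as.vector(outer(names(bands), c("EEG1", "EEG2", "EOG1",
                                                   "EOG2"),
                                   function(b, c_) paste(c_, b, sep = "_")))
  out
}

#' Nearest-centroid stage classifier on band powers
#'
#' Simple reference classifier: per-stage centroids of
#' [band_power_features()] in z-scored feature space; prediction is the
#' nearest centroid. Serves as an independent check that generated data
#' are separable.
#'
#' @param feat_train,y_train Training features and stage labels.
#' @param feat_test Features to classify.
#' @return A [hypnogram()] of predictions.
#' @export
nearest_centroid_stages <- function(feat_train, y_train, feat_test) {
  y <- .as_stage_int(y_train)
  mu <- colMeans(feat_train); sd_ <- apply(feat_train, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  zt <- sweep(sweep(feat_train, 2, mu), 2, sd_, `/`)
  zs <- sweep(sweep(feat_test, 2, mu), 2, sd_, `/`)
  cents <- t(vapply(0:4, function(s) colMeans(zt[y == s, , drop = FALSE]),
                    numeric(ncol(zt))))
  d2 <- outer(rowSums(zs^2), rowSums(cents^2), `+`) - 2 * zs %*% t(cents)
  hypnogram(max.col(-d2, ties.method = "first") - 1L)
}
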