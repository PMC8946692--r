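# Filtering and resampling chain applied to every recording before
# spectral analysis: powerline notch, 0.3-35 Hz Butterworth band-pass,
# then interpolation-based downsampling to 200 Hz.
#
# Both filters are applied forward-backward (zero-phase), so epoch
# boundaries are not shifted by filter group delay; the effective
# magnitude response is the squared single-pass response.

#' Filtering parameters
#'
#' Defaults follow standard PSG practice: a 50 Hz powerline notch (use 60
#' for recordings made on 60 Hz mains), and a 0.3-35 Hz band-pass that
#' keeps all AASM-relevant EEG/EOG rhythms while removing DC drift and
#' EMG/line contamination.
#'
#' @param notch_hz Powerline frequency to remove, usually 50 or 60.
#' @param notch_q Quality factor of the second-order notch (bandwidth =
#'   notch_hz / notch_q).
#' @param bp_low_hz,bp_high_hz Band-pass corner frequencies in Hz.
#' @param order Butterworth order of the band-pass prototype.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(notch_hz = 50, notch_q = 30,
                          bp_low_hz = 0.3, bp_high_hz = 35, order = 4) {
  if (bp_low_hz <= 0 || bp_low_hz >= bp_high_hz)
    stop("need 0 < bp_low_hz < bp_high_hz")
  structure(list(notch_hz = notch_hz, notch_q = notch_q,
                 bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz,
                 order = order),
            class = "filter_params")
}

# forward-backward (zero-phase) IIR filtering with odd-reflection edge
# extension and steady-state initial conditions, so constant inputs map
# to their DC steady state exactly and edge transients stay small
.filtfilt_ss <- function(b, a, x) {
  nb <- length(b); na_ <- length(a)
  dc <- sum(b) / sum(a)
  one_pass <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z0, nb - 1),
                              init.y = rep(z0 * dc, na_ - 1)))
  }
  L <- 3 * (max(nb, na_) - 1)
  n <- length(x)
  if (n <= L + 1) stop("signal too short for this filter's edge padding")
  front <- 2 * x[1] - x[seq(L + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - L)]
  xe <- c(front, x, back)
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(L + 1):(L + n)]
}

# RBJ-cookbook second-order IIR notch; returns list(b, a)
.design_notch <- function(notch_hz, notch_q, fs) {
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * notch_q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Remove powerline interference with a notch filter
#'
#' Second-order IIR notch at `params$notch_hz`, applied zero-phase
#' (forward-backward).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param params A [filter_params()].
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, params = filter_params()) {
  if (params$notch_hz >= fs / 2)
    stop("notch frequency ", params$notch_hz,
         " Hz is not below the Nyquist rate ", fs / 2, " Hz")
  d <- .design_notch(params$notch_hz, params$notch_q, fs)
  .filtfilt_ss(d$b, d$a, x)
}

#' Band-pass filter a signal
#'
#' Butterworth band-pass (default 4th order, 0.3-35 Hz), applied
#' zero-phase. The 0.3 Hz high-pass corner removes DC offset and slow
#' electrode drift; the 35 Hz low-pass corner rejects EMG and residual
#' line noise and makes a later 200 Hz sampling rate Nyquist-safe.
#'
#' @inheritParams notch_filter
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, params = filter_params()) {
  if (params$bp_high_hz >= fs / 2)
    stop("band-pass upper corner ", params$bp_high_hz,
         " Hz is not below the Nyquist rate ", fs / 2, " Hz")
  bt <- signal::butter(params$order,
                       c(params$bp_low_hz, params$bp_high_hz) / (fs / 2),
                       type = "pass")
  .filtfilt_ss(bt$b, bt$a, x)
}

#' Squared magnitude response of the zero-phase filters
#'
#' Utility for verifying attenuation: returns |H(f)|^2 (the effective
#' response of forward-backward application) of the notch or band-pass
#' filter at the requested frequencies.
#'
#' @param which `"notch"` or `"bandpass"`.
#' @param freqs_hz Frequencies at which to evaluate, Hz.
#' @inheritParams notch_filter
#' @return Numeric vector of linear magnitude gains.
#' @export
filter_response <- function(which = c("notch", "bandpass"), freqs_hz, fs,
                            params = filter_params()) {
  which <- match.arg(which)
  if (which == "notch") {
    d <- .design_notch(params$notch_hz, params$notch_q, fs)
    b <- d$b; a <- d$a
  } else {
    bt <- signal::butter(params$order,
                         c(params$bp_low_hz, params$bp_high_hz) / (fs / 2),
                         type = "pass")
    b <- bt$b; a <- bt$a
  }
  w <- 2 * pi * freqs_hz / fs
  z <- exp(-1i * w)
  H <- outer(z, seq_along(b) - 1, `^`) %*% b /
       (outer(z, seq_along(a) - 1, `^`) %*% a)
  as.numeric(Mod(H))^2
}

#' Downsample a signal by linear interpolation
#'
#' Evaluates the signal, by linear interpolation between native samples,
#' at the time points of the target rate: output sample k (0-based) is the
#' signal at time k / `fs_out`. Output length is
#' `floor(n * fs_out / fs_in)`. No separate anti-alias filter is applied;
#' the preceding 35 Hz band-pass already bounds content well below the
#' 100 Hz Nyquist frequency of the 200 Hz target rate.
#'
#' @param x Numeric signal vector sampled at `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates, Hz (`fs_out <=
#'   fs_in`; upsampling is not supported).
#' @return Numeric vector at rate `fs_out`.
#' @export
resample_by_interpolation <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in)
    stop("fs_out (", fs_out, ") exceeds fs_in (", fs_in,
         "); upsampling is not supported")
  if (fs_out <= 0) stop("fs_out must be positive")
  n <- length(x)
  if (fs_in == fs_out) return(x)
  m <- floor(n * fs_out / fs_in)
  t_out <- (seq_len(m) - 1) / fs_out
  stats::approx(x = (seq_len(n) - 1) / fs_in, y = x, xout = t_out,
                method = "linear", rule = 2)$y
}

#' Preprocess a whole recording
#'
#' Per channel, at the native rate: notch filter, then band-pass filter;
#' finally downsample to `target_fs` if the native rate is higher.
#' Filtering precedes resampling because the notch is defined at the
#' native powerline/sampling relationship.
#'
#' @param rec A [recording()].
#' @param params A [filter_params()].
#' @param target_fs Target sampling rate in Hz (default 200).
#' @return A preprocessed [recording()] at `target_fs`.
#' @export
preprocess_recording <- function(rec, params = filter_params(),
                                 target_fs = 200) {
  filt <- apply(rec$data, 2, function(ch)
    bandpass_filter(notch_filter(ch, rec$fs, params), rec$fs, params))
  if (rec$fs > target_fs) {
    filt <- apply(filt, 2, resample_by_interpolation,
                  fs_in = rec$fs, fs_out = target_fs)
    fs <- target_fs
  } else {
    fs <- rec$fs
  }
  recording(filt, channels = rec$channels, fs = fs)
}
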