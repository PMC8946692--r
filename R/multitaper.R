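# Multi-taper spectral estimation with DPSS (Slepian) tapers.
#
# The spectrogram convention is fixed so that a 30 s epoch of a 200 Hz
# channel yields a 30 x 103 time-by-frequency matrix: 5 s windows, 1 s
# step, NFFT = 1024 (next power of two of the 1000-sample window), and an
# inclusive 0-20 Hz band (bin width 200/1024 Hz, bins 0..102).

#' Multitaper parameters
#'
#' @param window_s Analysis window length in seconds.
#' @param step_s Window step in seconds.
#' @param nw Time-half-bandwidth product; spectral resolution is
#'   `2*nw/window_s` Hz.
#' @param k Number of tapers; must satisfy `k <= 2*nw - 1`.
#' @param fmin_hz,fmax_hz Retained frequency band (inclusive), Hz.
#' @return A list of class `mt_params`.
#' @export
mt_params <- function(window_s = 5, step_s = 1, nw = 5, k = 9,
                      fmin_hz = 0, fmax_hz = 20) {
  if (k > 2 * nw - 1)
    stop("taper count k = ", k, " exceeds 2*nw - 1 = ", 2 * nw - 1)
  if (step_s > window_s) stop("step_s must not exceed window_s")
  if (fmin_hz < 0 || fmin_hz >= fmax_hz) stop("need 0 <= fmin_hz < fmax_hz")
  structure(list(window_s = window_s, step_s = step_s, nw = nw, k = k,
                 fmin_hz = fmin_hz, fmax_hz = fmax_hz),
            class = "mt_params")
}

# cache for computed taper banks, keyed by n/nw/k
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (DPSS)
#'
#' Computes the first `k` Slepian tapers of length `n` for half-bandwidth
#' `W = nw/n` by eigendecomposition of the standard symmetric tridiagonal
#' commuting matrix, then orders them by their spectral concentration
#' (the fraction of taper energy inside the band, computed from the dense
#' sinc concentration kernel).
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product.
#' @param k Number of tapers (`k <= 2*nw - 1`).
#' @return A list of class `taper_bank`: `tapers` (n x k matrix,
#'   unit-norm columns, concentration-ordered) and `concentrations`
#'   (length-k, strictly decreasing, all in (0,1)).
#' @export
compute_dpss <- function(n, nw, k) {
  if (k > 2 * nw - 1)
    stop("taper count k = ", k, " exceeds 2*nw - 1 = ", 2 * nw - 1)
  if (n < k || k < 1) stop("need n >= k >= 1")
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(got <- .dpss_cache[[key]])) return(got)

  W <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  Tm <- matrix(0, n, n)
  Tm[cbind(i + 1, i + 1)] <- diag_v
  Tm[cbind(1:(n - 1), 2:n)] <- off_v
  Tm[cbind(2:n, 1:(n - 1))] <- off_v
  eg <- eigen(Tm, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]

  # unit norm and a fixed sign convention (positive mean, else positive
  # leading slope) so results are bit-reproducible
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    s <- sum(v)
    if (abs(s) > 1e-10) { if (s < 0) v <- -v }
    else if (v[2] - v[1] < 0) v <- -v
    V[, j] <- v
  }

  # concentrations via the defining quadratic form with the sinc kernel
  m <- outer(i, i, `-`)
  S <- sin(2 * pi * W * m) / (pi * m)
  S[cbind(i + 1, i + 1)] <- 2 * W
  lam <- vapply(seq_len(k), function(j) sum(V[, j] * (S %*% V[, j])), 0)
  ord <- order(lam, decreasing = TRUE)

  bank <- structure(list(tapers = V[, ord, drop = FALSE],
                         concentrations = lam[ord], n = n, nw = nw, k = k),
                    class = "taper_bank")
  .dpss_cache[[key]] <- bank
  bank
}

# one-sided multitaper PSD of a matrix of windows (n x m), averaged over
# tapers; returns (nfft/2 + 1) x m. Scaling: PSD = |X|^2 / fs two-sided,
# folded; integral over frequency then matches window power (Parseval).
.mt_psd_mat <- function(wins, bank, nfft, fs) {
  n <- nrow(wins); m <- ncol(wins)
  half <- nfft %/% 2 + 1
  acc <- matrix(0, half, m)
  for (j in seq_len(bank$k)) {
    tap <- wins * bank$tapers[, j]
    if (nfft > n) tap <- rbind(tap, matrix(0, nfft - n, m))
    X <- stats::mvfft(tap)
    P <- (Mod(X[seq_len(half), , drop = FALSE])^2) / fs
    acc <- acc + P
  }
  acc <- acc / bank$k
  if (half > 2) acc[2:(nfft %/% 2), ] <- 2 * acc[2:(nfft %/% 2), ]
  acc
}

#' Multitaper power spectral density of one window
#'
#' Average of the `k` single-taper spectra, folded to one side, in units
#' of power per Hz. Integrating the PSD over frequency recovers the
#' window's mean power.
#'
#' @param x Numeric window; its length must equal the taper length.
#' @param bank A [compute_dpss()] taper bank.
#' @param nfft FFT length (default: next power of two of `length(x)`).
#' @param fs Sampling rate in Hz.
#' @return List with `psd` (length `nfft/2 + 1`) and `freqs_hz`.
#' @export
multitaper_psd <- function(x, bank, nfft = NULL, fs) {
  if (length(x) != bank$n)
    stop("window length ", length(x), " does not match taper length ",
         bank$n)
  if (is.null(nfft)) nfft <- max(2^ceiling(log2(length(x))), length(x))
  psd <- .mt_psd_mat(matrix(x, ncol = 1), bank, nfft, fs)[, 1]
  list(psd = psd, freqs_hz = (0:(nfft %/% 2)) * fs / nfft)
}

# remove a per-column linear trend (least squares) from a window matrix
.detrend_linear <- function(wins) {
  n <- nrow(wins)
  t_ <- seq_len(n) - (n + 1) / 2
  beta <- crossprod(t_, wins) / sum(t_^2)    # slope per column
  mu <- colMeans(wins)
  wins - rep(mu, each = n) - t_ %*% beta
}

#' Multitaper spectrogram of a recording
#'
#' Windows are placed at integer multiples of `step_s` starting at time 0;
#' the tail is reflection-padded by `window_s - step_s` seconds so that a
#' recording of T whole seconds yields exactly `T / step_s` columns — and
#' therefore every 30 s epoch owns exactly 30 columns at the default 1 s
#' step. Each window is linearly detrended before tapering to keep
#' within-window drift out of the delta band. NFFT is the next power of
#' two of the window sample count; the frequency axis is restricted to
#' `[fmin_hz, fmax_hz]` inclusive.
#'
#' @param rec A [recording()] (or a single numeric vector with `fs` given).
#' @param params An [mt_params()].
#' @param fs Sampling rate, only needed when `rec` is a bare vector.
#' @return For a recording: a named list (one entry per channel) of
#'   `mt_spectrogram` objects; for a vector: a single `mt_spectrogram`.
#'   Each has `values` (time x frequency power matrix, µV²/Hz), `times_s`
#'   (window start times) and `freqs_hz`.
#' @export
multitaper_spectrogram <- function(rec, params = mt_params(), fs = NULL) {
  if (inherits(rec, "psg_recording")) {
    out <- lapply(seq_along(rec$channels), function(j)
      .mt_channel(rec$data[, j], rec$fs, params))
    names(out) <- rec$channels
    return(out)
  }
  if (is.null(fs)) stop("fs must be given when rec is a plain vector")
  .mt_channel(as.numeric(rec), fs, params)
}

.mt_channel <- function(x, fs, params) {
  nwin <- params$window_s * fs
  if (nwin != round(nwin))
    stop("fs * window_s must be an integer number of samples")
  nwin <- as.integer(nwin)
  if (length(x) < nwin)
    stop("recording (", length(x) / fs, " s) is shorter than one window (",
         params$window_s, " s)")
  step <- params$step_s * fs
  if (step != round(step)) stop("fs * step_s must be an integer")
  step <- as.integer(step)

  dur <- floor(length(x) / fs)
  starts <- seq(0, dur * fs - step, by = step)        # sample offsets
  pad_n <- nwin - step
  xp <- c(x, rev(x[(length(x) - pad_n + 1):length(x)]))

  bank <- compute_dpss(nwin, params$nw, params$k)
  nfft <- max(2^ceiling(log2(nwin)), nwin)
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  keep <- which(freqs >= params$fmin_hz & freqs <= params$fmax_hz)

  chunk <- 2048L
  vals <- matrix(0, length(starts), length(keep))
  for (lo in seq(1L, length(starts), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(starts))
    idx <- outer(seq_len(nwin), starts[lo:hi], `+`)
    wins <- matrix(xp[idx], nrow = nwin)
    wins <- .detrend_linear(wins)
    psd <- .mt_psd_mat(wins, bank, nfft, fs)
    vals[lo:hi, ] <- t(psd[keep, , drop = FALSE])
  }
  structure(list(values = vals, times_s = starts / fs,
                 freqs_hz = freqs[keep], params = params, fs = fs),
            class = "mt_spectrogram")
}

#' @export
print.mt_spectrogram <- function(x, ...) {
  cat("<mt_spectrogram> ", nrow(x$values), " time bins x ",
      ncol(x$values), " frequency bins (",
      min(x$freqs_hz), "-", max(x$freqs_hz), " Hz)\n", sep = "")
  invisible(x)
}
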