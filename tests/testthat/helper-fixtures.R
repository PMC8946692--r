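# Shared fixtures, generated in code and cached for the duration of one
# test run so expensive synthetic datasets are built only once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# balanced hypnogram: n_per epochs of every stage, shuffled
balanced_hypnogram <- function(n_per, seed = 1) {
  set.seed(seed)
  hypnogram(sample(rep(0:4, each = n_per)))
}

# small preprocessed synthetic recording (10 epochs/stage) + labels
small_synth <- function() cached("small_synth", {
  h <- balanced_hypnogram(10, seed = 21)
  rec <- synthesize_recording(h, synth_config(seed = 21))
  list(rec = preprocess_recording(rec), h = h)
})

# periodogram band-power fraction in [lo, hi) Hz — independent of the
# package's multitaper code
periodogram_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  half <- floor(n / 2)
  p <- Mod(X[seq_len(half)])^2
  f <- (seq_len(half) - 1) * fs / n
  sum(p[f >= lo & f < hi]) / sum(p)
}

# numerical gradient of scalar-valued fn at x[i]
num_grad_at <- function(fn, x, i, eps = 1e-5) {
  x1 <- x; x1[i] <- x1[i] + eps
  x2 <- x; x2[i] <- x2[i] - eps
  (fn(x1) - fn(x2)) / (2 * eps)
}
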