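# Synthetic polysomnography generator: Markov hypnogram statistics,
# stage-specific spectral content (checked with independent
# periodograms), determinism, amplitude realism and separability.

test_that("the Markov hypnogram follows its transition matrix", {
  cfg_id <- synth_config(n_epochs = 50, transition = diag(5))
  expect_equal(as.integer(simulate_hypnogram(cfg_id)),
               rep(0L, 50))                 # W is absorbing at start

  unif <- matrix(0.2, 5, 5)
  cfg_u <- synth_config(n_epochs = 10000, transition = unif, seed = 61)
  freq <- table(factor(as.integer(simulate_hypnogram(cfg_u)),
                       levels = 0:4)) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))

  h1 <- simulate_hypnogram(synth_config(n_epochs = 100, seed = 3))
  h2 <- simulate_hypnogram(synth_config(n_epochs = 100, seed = 3))
  expect_identical(as.integer(h1), as.integer(h2))

  bad <- diag(5); bad[1, 1] <- 0.5
  expect_error(synth_config(transition = bad), "sum to 1")
})

test_that("long-run stage frequencies match the stationary distribution", {
  # self-transitions of 0.8 make epoch labels strongly autocorrelated,
  # so frequencies need a long chain to settle near the eigenvector
  cfg <- synth_config(n_epochs = 20000, seed = 62)
  h <- simulate_hypnogram(cfg)
  freq <- as.numeric(table(factor(as.integer(h), levels = 0:4)) / 20000)
  pi_ <- stationary_distribution(cfg$transition)   # eigenvector oracle
  expect_true(all(abs(freq - pi_) < 0.03))
  expect_equal(sum(pi_), 1, tolerance = 1e-12)
})

test_that("stage signals carry their defining spectral signatures", {
  fs <- 200
  n3 <- synthesize_stage_signal("N3", 30, fs, seed = 63)
  w <- synthesize_stage_signal("W", 30, fs, seed = 63)
  expect_equal(dim(n3), c(4, 6000))
  expect_equal(dim(synthesize_stage_signal(0, 12.5, fs, seed = 1)),
               c(4, 2500))

  # independent periodogram oracle: N3 EEG is delta-dominated vs W
  d_n3 <- periodogram_band_fraction(n3[1, ], fs, 0.5, 2)
  d_w <- periodogram_band_fraction(w[1, ], fs, 0.5, 2)
  expect_gt(d_n3, d_w)

  # W EEG is alpha-rich vs N3
  a_w <- periodogram_band_fraction(w[1, ], fs, 8, 12)
  a_n3 <- periodogram_band_fraction(n3[1, ], fs, 8, 12)
  expect_gt(a_w, a_n3)

  # N2 carries sigma-band spindle power in EEG
  n2 <- synthesize_stage_signal("N2", 30, fs, seed = 64)
  n1 <- synthesize_stage_signal("N1", 30, fs, seed = 64)
  expect_gt(periodogram_band_fraction(n2[1, ], fs, 12, 15),
            periodogram_band_fraction(n1[1, ], fs, 12, 15))

  # R: antiphase EOG deflections make the two EOG channels anticorrelate
  r <- synthesize_stage_signal("R", 30, fs, seed = 65)
  expect_lt(stats::cor(r[3, ], r[4, ]), 0)

  expect_error(synthesize_stage_signal(9, 30, fs), "unknown stage")
})

test_that("generated datasets are reproducible with aligned labels", {
  cfg <- synth_config(n_epochs = 40, seed = 66)
  ds <- generate_dataset(cfg, n_recordings = 2)
  expect_length(ds, 2)
  expect_equal(ds[[1]]$recording$duration_s, 1200)
  expect_length(ds[[1]]$hypnogram, 40)

  ds2 <- generate_dataset(cfg, n_recordings = 2)
  expect_identical(ds[[1]]$recording$data, ds2[[1]]$recording$data)
  expect_identical(as.integer(ds[[1]]$hypnogram),
                   as.integer(ds2[[1]]$hypnogram))
  # distinct recordings are not identical
  expect_false(identical(ds[[1]]$recording$data, ds[[2]]$recording$data))

  cfg250 <- synth_config(n_epochs = 2, fs = 250, seed = 66)
  rec250 <- generate_dataset(cfg250, 1)[[1]]$recording
  expect_equal(nrow(rec250$data), 2 * 7500)  # 30 s epochs at 250 Hz
})

test_that("per-channel amplitudes stay in the physiological range", {
  for (stage in 0:4) {
    seg <- synthesize_stage_signal(stage, 30, 200, seed = 70 + stage)
    rms <- sqrt(rowMeans(seg^2))
    expect_true(all(rms > 5 & rms < 150),
                label = paste("stage", stage, "RMS in 5-150 uV"))
  }
})

test_that("synthetic recordings round-trip through the EDF reader", {
  h <- balanced_hypnogram(1, seed = 71)
  rec <- synthesize_recording(h, synth_config(seed = 71))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, rec$channels)
  expect_equal(back$fs, rec$fs)
  tol <- max(apply(rec$data, 2, function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(back$data - rec$data)), 1.01 * tol + 1e-9)
})

test_that("stages are separable by band-power nearest centroids", {
  h_train <- balanced_hypnogram(50, seed = 72)   # 250 training epochs
  h_test <- balanced_hypnogram(100, seed = 73)   # 500 held-out epochs
  rec_train <- synthesize_recording(h_train, synth_config(seed = 72))
  rec_test <- synthesize_recording(h_test, synth_config(seed = 73))
  ft <- band_power_features(rec_train)
  fs_ <- band_power_features(rec_test)
  pred <- nearest_centroid_stages(ft, h_train, fs_)
  expect_gt(stage_accuracy(pred, h_test), 0.8)
})
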