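# Epoch slicing, four-channel tiling, raster rendering and model-input
# normalization.

fake_spec <- function(n_times, n_freqs = 103) {
  structure(list(values = matrix(stats::runif(n_times * n_freqs, 1, 10),
                                 n_times, n_freqs),
                 times_s = seq_len(n_times) - 1,
                 freqs_hz = seq(0, 20, length.out = n_freqs),
                 params = mt_params(), fs = 200),
            class = "mt_spectrogram")
}

test_that("spectrograms slice into whole 30-row epochs", {
  sl <- segment_epochs(fake_spec(300))
  expect_length(sl, 10)
  expect_true(all(vapply(sl, function(s) identical(dim(s), c(30L, 103L)),
                         TRUE)))

  expect_warning(sl5 <- segment_epochs(fake_spec(305)), "discarded")
  expect_length(sl5, 10)

  expect_error(segment_epochs(fake_spec(29)), "time bins")
})

test_that("four-channel tiling uses the 2x2 block layout", {
  ms <- lapply(1:4, function(i) matrix(i * 100 + seq_len(30 * 103),
                                       30, 103))
  tiled <- tile_four_channels(ms)
  expect_equal(dim(tiled), c(60, 206))
  expect_equal(tiled[1, 1], ms[[1]][1, 1])
  expect_equal(tiled[1, 104], ms[[2]][1, 1])
  expect_equal(tiled[31, 1], ms[[3]][1, 1])
  expect_equal(tiled[31, 104], ms[[4]][1, 1])
  # information preserving: every block recovers its source
  expect_equal(tiled[1:30, 1:103], ms[[1]])
  expect_equal(tiled[31:60, 104:206], ms[[4]])

  expect_error(tile_four_channels(ms[1:3]), "four")
  ms[[2]] <- ms[[2]][, 1:50]
  expect_error(tile_four_channels(ms), "mismatched")
})

test_that("rendering produces 256x256 rasters with a monotone colormap", {
  tiled <- matrix(stats::runif(60 * 206, 1, 100), 60, 206)
  norm <- display_range(tiled)
  ras <- render_epoch_image(tiled, norm)
  expect_equal(dim(ras), c(256L, 256L, 3L))
  expect_true(all(ras >= 0 & ras <= 255))

  flat <- render_epoch_image(matrix(5, 60, 206), norm)
  for (c_ in 1:3) expect_equal(length(unique(as.vector(flat[, , c_]))), 1L)

  # jet lookup is injective and ordered cold -> hot: every value gets a
  # distinct color, blue dominates the low end, red the high end
  v <- seq(0, 1, length.out = 101)
  lut <- somnostage:::.jet(v)
  expect_equal(nrow(unique(lut)), length(v))
  expect_true(all(diff(lut[v <= 0.75, 1]) >= 0))   # red ramps up
  expect_true(all(diff(lut[v >= 0.25, 3]) <= 0))   # blue ramps down
  expect_true(all(lut[v < 0.25, 3] > lut[v < 0.25, 1]))
  expect_true(all(lut[v > 0.75, 1] > lut[v > 0.75, 3]))

  bad <- tiled; bad[5, 5] <- NaN
  expect_error(render_epoch_image(bad, norm), "non-finite")
  expect_error(render_epoch_image(tiled, c(3, 3)), "low < high")
})

test_that("model inputs are 64x64x3 in [0,1]", {
  tiled <- matrix(stats::runif(60 * 206, 1, 100), 60, 206)
  ras <- render_epoch_image(tiled, display_range(tiled))
  inp <- prepare_model_input(ras)
  expect_equal(dim(inp), c(64, 64, 3))
  expect_true(all(inp >= 0 & inp <= 1))

  expect_equal(prepare_model_input(array(0L, c(256, 256, 3))),
               array(0, c(64, 64, 3)))
  expect_error(prepare_model_input(array(0, c(64, 64, 3))), "256")

  # deterministic for fixed input and range
  expect_identical(inp, prepare_model_input(ras))
})

test_that("raw epoching yields 4x6000 blocks and drops partial tails", {
  set.seed(41)
  rec <- recording(matrix(rnorm(310 * 200 * 4), ncol = 4),
                   channels = c("EEG1", "EEG2", "EOG1", "EOG2"), fs = 200)
  eps <- segment_raw_epochs(rec)
  expect_length(eps, 10)                  # 310 s -> 10 full epochs
  expect_equal(dim(eps[[1]]$samples), c(4, 6000))
  expect_equal(eps[[3]]$epoch_index, 3)
  # values land in the right epoch, channels in rows
  expect_equal(eps[[2]]$samples[3, 1], rec$data[6001, 3])

  rec2 <- recording(matrix(rnorm(12000 * 2), ncol = 2),
                    channels = c("a", "b"), fs = 200)
  expect_error(segment_raw_epochs(rec2), "4 channels")
  rec250 <- recording(matrix(rnorm(15000 * 4), ncol = 4),
                      channels = c("a", "b", "c", "d"), fs = 250)
  expect_error(segment_raw_epochs(rec250), "200 Hz")
})

test_that("spectrogram and raw paths agree on the epoch count", {
  s <- small_synth()
  n_raw <- length(segment_raw_epochs(s$rec))
  specs <- multitaper_spectrogram(s$rec)
  n_spec <- length(segment_epochs(specs[[1]]))
  expect_equal(n_spec, n_raw)
  expect_equal(n_raw, length(s$h))
})

test_that("epoch_images builds normalized inputs for every epoch", {
  s <- small_synth()
  sub <- recording(s$rec$data[1:(5 * 6000), ], channels = s$rec$channels,
                   fs = 200)
  ei <- epoch_images(sub, return_rasters = TRUE)
  expect_equal(dim(ei$inputs), c(64, 64, 3, 5))
  expect_true(all(ei$inputs >= 0 & ei$inputs <= 1))
  expect_length(ei$rasters, 5)
  png_path <- tempfile(fileext = ".png")
  write_epoch_png(ei$rasters[[1]], png_path)
  expect_equal(dim(png::readPNG(png_path)), c(256, 256, 3))
})
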