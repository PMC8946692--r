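# Conversion of spectrograms and raw signals into per-epoch model inputs:
# 30 x 103 slices, 2x2 four-channel tiling (60 x 206), jet-colormapped
# 256 x 256 rasters, 64 x 64 x 3 normalized inputs, and 4 x 6000 raw
# epoch matrices.

#' Slice a spectrogram into 30-second epochs
#'
#' @param spec An `mt_spectrogram` whose columns follow the 1-per-second
#'   placement of [multitaper_spectrogram()].
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return List of time-by-frequency matrices, one per complete epoch
#'   (30 rows each at the default step); a trailing partial epoch is
#'   dropped with a warning.
#' @export
segment_epochs <- function(spec, epoch_len_s = 30) {
  per <- as.integer(epoch_len_s / spec$params$step_s)
  nt <- nrow(spec$values)
  if (nt < per)
    stop("spectrogram has ", nt, " time bins; one epoch needs ", per)
  nfull <- nt %/% per
  if (nt %% per != 0L)
    warning(nt %% per, " trailing spectrogram column(s) discarded ",
            "(incomplete epoch)")
  lapply(seq_len(nfull), function(e)
    spec$values[((e - 1L) * per + 1L):(e * per), , drop = FALSE])
}

#' Tile four channel spectrograms into one matrix
#'
#' 2x2 block layout: channel 1 top-left, channel 2 top-right, channel 3
#' bottom-left, channel 4 bottom-right (EEG1, EEG2, EOG1, EOG2). Four
#' 30 x 103 inputs give a 60 x 206 output.
#'
#' @param slices List of exactly four matrices of identical dimensions.
#' @return A single matrix with doubled rows and columns.
#' @export
tile_four_channels <- function(slices) {
  if (length(slices) != 4L)
    stop("exactly four channel slices are required, got ", length(slices))
  d <- dim(slices[[1]])
  for (s in slices)
    if (!identical(dim(s), d)) stop("channel slices have mismatched shapes")
  rbind(cbind(slices[[1]], slices[[2]]),
        cbind(slices[[3]], slices[[4]]))
}

# jet-like colormap lookup: v in [0,1] -> RGB in [0,1]
.jet <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

# bilinear resize of a 2D matrix to nr x nc (EBImage backend)
.resize_bilinear <- function(m, nr, nc) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = nr, h = nc,
                                     filter = "bilinear"))
}

#' Display normalization range of a set of spectrogram powers
#'
#' The 5th-95th percentile of the dB-transformed power over everything
#' passed in. Computed per recording (not per epoch) so that absolute
#' amplitude differences between epochs — e.g. high-voltage delta in N3 —
#' survive into the rendered images.
#'
#' @param ... Spectrogram power matrices, `mt_spectrogram` objects or
#'   lists of either.
#' @param probs Two quantile probabilities (default `c(0.05, 0.95)`).
#' @return Numeric length-2 vector `c(low, high)` in dB.
#' @export
display_range <- function(..., probs = c(0.05, 0.95)) {
  grab <- function(x) {
    if (inherits(x, "mt_spectrogram")) return(list(x$values))
    if (is.list(x)) return(do.call(c, lapply(x, grab)))
    list(x)
  }
  vals <- unlist(grab(list(...)), use.names = FALSE)
  db <- 10 * log10(vals + 1e-12)
  q <- stats::quantile(db, probs = probs, names = FALSE)
  if (q[2] - q[1] < 1e-9) q[2] <- q[1] + 1e-9
  q
}

#' Render a tiled epoch spectrogram as a 256 x 256 RGB raster
#'
#' Power is dB-transformed (`10*log10(p + 1e-12)`), clipped to the display
#' range, mapped through a jet-like colormap and stretched (anisotropic
#' bilinear) to a square 256 x 256 raster, the size used as the stored
#' image representation of one epoch.
#'
#' @param tiled Numeric power matrix (normally 60 x 206 from
#'   [tile_four_channels()]); all cells must be finite.
#' @param norm Length-2 dB display range `c(low, high)` from
#'   [display_range()].
#' @return Integer-valued array 256 x 256 x 3 with values in 0..255.
#' @export
render_epoch_image <- function(tiled, norm) {
  if (!all(is.finite(tiled))) stop("tiled spectrogram has non-finite cells")
  if (norm[1] >= norm[2]) stop("display range must satisfy low < high")
  db <- 10 * log10(tiled + 1e-12)
  v <- (db - norm[1]) / (norm[2] - norm[1])
  v <- pmin(pmax(v, 0), 1)
  rgb_ <- .jet(as.vector(v))
  out <- array(0, dim = c(256, 256, 3))
  for (c_ in 1:3) {
    plane <- matrix(rgb_[, c_], nrow = nrow(tiled))
    out[, , c_] <- .resize_bilinear(plane, 256, 256)
  }
  out <- round(pmin(pmax(out, 0), 1) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Prepare the network input from a rendered raster
#'
#' Bilinear downscale of the 256 x 256 x 3 raster to 64 x 64 x 3 and
#' normalization to [0,1] by dividing by 255.
#'
#' @param raster 256 x 256 x 3 array with values in 0..255.
#' @return 64 x 64 x 3 double array with values in [0, 1].
#' @export
prepare_model_input <- function(raster) {
  d <- dim(raster)
  if (length(d) != 3L || d[1] != 256L || d[2] != 256L || d[3] != 3L)
    stop("raster must be 256 x 256 x 3, got ",
         paste(d, collapse = " x "))
  out <- array(0, dim = c(64, 64, 3))
  for (c_ in 1:3)
    out[, , c_] <- .resize_bilinear(raster[, , c_], 64, 64)
  pmin(pmax(out / 255, 0), 1)
}

#' Write an epoch raster to a PNG file
#'
#' @param raster 256 x 256 x 3 array in 0..255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_epoch_png <- function(raster, path) {
  png::writePNG(raster / 255, target = path)
  invisible(path)
}

#' Segment a preprocessed recording into raw 4 x 6000 epochs
#'
#' @param rec A 4-channel [recording()] at exactly 200 Hz.
#' @return List of `raw_epoch` objects, each with `samples` (4 x 6000
#'   matrix, channels in rows) and `epoch_index` (1-based); a trailing
#'   partial epoch is dropped.
#' @export
segment_raw_epochs <- function(rec) {
  if (length(rec$channels) != 4L)
    stop("raw epoching requires exactly 4 channels, got ",
         length(rec$channels))
  if (rec$fs != 200)
    stop("raw epoching requires fs = 200 Hz, got ", rec$fs,
         " (preprocess/resample first)")
  n_ep <- nrow(rec$data) %/% 6000L
  if (n_ep < 1L) stop("recording shorter than one 30 s epoch")
  lapply(seq_len(n_ep), function(e) {
    rows <- ((e - 1L) * 6000L + 1L):(e * 6000L)
    structure(list(samples = t(rec$data[rows, , drop = FALSE]),
                   epoch_index = e),
              class = "raw_epoch")
  })
}

#' Build per-epoch model inputs for a whole recording
#'
#' Full spectrogram-image chain for one preprocessed recording: multitaper
#' spectrogram per channel, epoch slicing, 2x2 tiling, rendering with a
#' recording-level display range, and 64 x 64 x 3 normalization.
#'
#' @param rec A preprocessed 4-channel [recording()] at 200 Hz.
#' @param params An [mt_params()].
#' @param return_rasters If TRUE also keep the 256 x 256 rasters.
#' @return List with `inputs` (64 x 64 x 3 x n_epochs array), `norm`
#'   (display range used), and optionally `rasters` (list).
#' @export
epoch_images <- function(rec, params = mt_params(), return_rasters = FALSE) {
  if (length(rec$channels) != 4L)
    stop("spectrogram tiling requires exactly 4 channels")
  specs <- multitaper_spectrogram(rec, params)
  norm <- display_range(specs)
  sliced <- lapply(specs, segment_epochs)
  n_ep <- min(lengths(sliced))
  inputs <- array(0, dim = c(64, 64, 3, n_ep))
  rasters <- if (return_rasters) vector("list", n_ep) else NULL
  for (e in seq_len(n_ep)) {
    tiled <- tile_four_channels(lapply(sliced, `[[`, e))
    ras <- render_epoch_image(tiled, norm)
    inputs[, , , e] <- prepare_model_input(ras)
    if (return_rasters) rasters[[e]] <- ras
  }
  out <- list(inputs = inputs, norm = norm)
  if (return_rasters) out$rasters <- rasters
  out
}
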