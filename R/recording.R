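#' @keywords internal
"_PACKAGE"

#' Canonical AASM sleep-stage labels
#'
#' The five stages, in the fixed order used everywhere in this package
#' (stage indices, confusion-matrix rows/columns, classifier outputs):
#' W = 0, N1 = 1, N2 = 2, N3 = 3, R = 4.
#'
#' @return Character vector `c("W","N1","N2","N3","R")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' Construct a sleep-stage hypnogram
#'
#' A hypnogram is a sequence of stage labels, one per 30-second epoch,
#' stored as integer codes 0..4 in the fixed W,N1,N2,N3,R order.
#'
#' @param stages Integer vector of stage codes in 0..4, or a character
#'   vector of stage names (`"W","N1","N2","N3","R"`).
#' @param epoch_len_s Epoch length in seconds; only 30 is valid.
#' @return Object of class `hypnogram`: an integer vector with attribute
#'   `epoch_len_s`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  if (epoch_len_s != 30)
    stop("hypnogram epochs are 30 s by definition; got ", epoch_len_s)
  if (is.character(stages)) {
    idx <- match(stages, stage_levels())
    if (anyNA(idx))
      stop("unknown stage label(s): ",
           paste(unique(stages[is.na(idx)]), collapse = ", "))
    stages <- idx - 1L
  }
  stages <- as.integer(stages)
  if (length(stages) < 1L) stop("hypnogram must contain at least one epoch")
  if (any(stages < 0L | stages > 4L))
    stop("stage codes must lie in 0..4 (W,N1,N2,N3,R)")
  structure(stages, epoch_len_s = 30, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x), " epochs (", length(x) * 30 / 60,
      " min)\n", sep = "")
  tab <- table(factor(stage_levels()[unclass(x) + 1L], levels = stage_levels()))
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) {
  hypnogram(unclass(x)[i])
}

#' Stage names of a hypnogram
#' @param h A `hypnogram`.
#' @return Character vector of stage names.
#' @export
stage_names <- function(h) stage_levels()[as.integer(h) + 1L]

#' Construct a multi-channel recording
#'
#' Container for a polysomnography recording: a samples-by-channels matrix
#' in microvolts plus a sampling rate. All channels share one length.
#'
#' @param data Numeric matrix, samples in rows, one column per channel, or a
#'   named list of equal-length numeric vectors.
#' @param channels Character vector of channel names (defaults to the
#'   column/list names of `data`).
#' @param fs Sampling rate in Hz (> 0).
#' @return Object of class `psg_recording` with elements `data` (matrix),
#'   `channels`, `fs` and `duration_s`.
#' @export
recording <- function(data, channels = NULL, fs) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(channels)) channels <- names(data)
    n <- unique(lengths(data))
    if (length(n) != 1L) stop("all channels must have the same length")
    data <- do.call(cbind, data)
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) channels <- colnames(data)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(ncol(data)))
  if (length(channels) != ncol(data))
    stop("channel name count (", length(channels),
         ") does not match column count (", ncol(data), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  colnames(data) <- channels
  structure(
    list(data = data, channels = channels, fs = fs,
         duration_s = nrow(data) / fs),
    class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", length(x$channels), " channel(s) x ",
      nrow(x$data), " samples @ ", x$fs, " Hz (",
      round(x$duration_s, 2), " s)\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

# normalize a channel name for matching: case/whitespace-insensitive
.norm_channel <- function(x) tolower(gsub("[[:space:]]+", "", x))

#' Select channels from a recording
#'
#' Matching is case-insensitive and ignores whitespace (EDF headers are
#' inconsistently padded). The output channel order follows `wanted`, not
#' the stored order.
#'
#' @param rec A `psg_recording`.
#' @param wanted Character vector of channel names to keep, in order.
#' @return A `psg_recording` with the requested channels.
#' @export
select_channels <- function(rec, wanted) {
  idx <- match(.norm_channel(wanted), .norm_channel(rec$channels))
  if (anyNA(idx))
    stop("channel(s) not found: ",
         paste(wanted[is.na(idx)], collapse = ", "),
         " (available: ", paste(rec$channels, collapse = ", "), ")")
  recording(rec$data[, idx, drop = FALSE], channels = wanted, fs = rec$fs)
}
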