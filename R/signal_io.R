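# Readers and writers for recordings and stage annotations.
#
# EDF here is the plain 16-bit European Data Format (one record duration,
# integer samples-per-record). Only the signal payload is interpreted;
# EDF+ annotation streams are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  vapply(x, function(xi) {
    s <- formatC(xi, format = "fg", width = 1)
    if (nchar(s) > width) s <- substr(s, 1, width)
    .edf_pad(s, width)
  }, "")
}

#' Write a recording to an EDF file
#'
#' Encodes each channel over its own physical range into 16-bit integers
#' (digital range -32768..32767). Record duration is 1 s, so `fs` must be
#' a whole number and the recording is truncated to whole seconds.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param physical_dim Physical dimension string stored per channel.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- length(rec$channels)
  n_rec <- floor(nrow(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  dat <- rec$data[seq_len(n_rec * fs), , drop = FALSE]

  # integer physical bounds: exactly representable in the 8-char ASCII
  # header fields, so encode and decode use identical ranges
  pmin_ <- floor(apply(dat, 2, min)); pmax_ <- ceiling(apply(dat, 2, max))
  flat <- pmax_ - pmin_ < 1
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))
  wr(.edf_pad("X X X X", 80))
  wr(.edf_pad("Startdate X X X X", 80))
  wr(.edf_pad("01.01.00", 8)); wr(.edf_pad("00.00.00", 8))
  wr(.edf_num(256L * (1L + ns), 8))
  wr(.edf_pad("", 44))
  wr(.edf_num(n_rec, 8)); wr(.edf_num(1, 8)); wr(.edf_num(ns, 4))
  for (ch in rec$channels) wr(.edf_pad(ch, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_pad(physical_dim, 8))
  for (i in seq_len(ns)) wr(.edf_num(pmin_[i], 8))
  for (i in seq_len(ns)) wr(.edf_num(pmax_[i], 8))
  for (i in seq_len(ns)) wr(.edf_num(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_num(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_num(fs, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  # physical -> digital, rounded; stored record-by-record, channel blocks
  pmin_w <- pmin_; pmax_w <- pmax_
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((dat[rows, i] - pmin_w[i]) / (pmax_w[i] - pmin_w[i]) *
                     (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read selected channels from an EDF file
#'
#' @param path Path to an EDF file.
#' @param wanted_channels Channel names to extract, in the desired output
#'   order. Matching is case-insensitive with whitespace stripped.
#' @return A [recording()] in microvolts (mV channels are converted).
#' @export
read_edf <- function(path, wanted_channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < n)
      stop("not a valid EDF file (truncated header): ", path)
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("not a valid EDF file (bad version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header byte count (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file (bad signal count)")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  if (is.null(wanted_channels)) wanted_channels <- labels
  sel <- match(.norm_channel(wanted_channels), .norm_channel(labels))
  if (anyNA(sel))
    stop("channel(s) not found in EDF: ",
         paste(wanted_channels[is.na(sel)], collapse = ", "),
         " (file has: ", paste(labels, collapse = ", "), ")")
  fs_sel <- spr[sel] / rec_dur
  if (length(unique(fs_sel)) != 1L)
    stop("selected channels have differing sampling rates")

  per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = n_rec * per_rec, size = 2,
                 endian = "little")
  if (length(raw) < n_rec * per_rec)
    stop("not a valid EDF file (truncated data): ", path)
  offs <- c(0L, cumsum(spr))
  out <- matrix(0, nrow = n_rec * spr[sel[1]], ncol = length(sel))
  for (j in seq_along(sel)) {
    i <- sel[j]
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]),
                           (seq_len(n_rec) - 1L) * per_rec, `+`))
    gain <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    phys <- (raw[idx] - dmin[i]) * gain + pmin_[i]
    if (grepl("^mv$", tolower(dims[i]))) phys <- phys * 1000
    out[, j] <- phys
  }
  recording(out, channels = wanted_channels, fs = fs_sel[1])
}

#' Read a delimited-text recording
#'
#' One numeric column per channel, whitespace- or comma-delimited, no
#' header. Used for lab-logger style recordings.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel names, one per column.
#' @return A [recording()].
#' @export
read_table_recording <- function(path, fs, channel_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- ""
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty recording file: ", path)
  if (grepl(",", first)) sep <- ","
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop("malformed recording table (", conditionMessage(e),
                             "): ", path))
  if (nrow(tab) == 0L) stop("empty recording file: ", path)
  if (ncol(tab) != length(channel_names))
    stop("file has ", ncol(tab), " columns but ", length(channel_names),
         " channel names were given")
  recording(as.matrix(tab), channels = channel_names, fs = fs)
}

# token -> stage code; covers AASM text labels and ISRUC-style numeric codes
# (some exports encode R as 5)
.stage_aliases <- c(
  "W" = 0, "WAKE" = 0, "AW" = 0, "0" = 0,
  "N1" = 1, "S1" = 1, "1" = 1,
  "N2" = 2, "S2" = 2, "2" = 2,
  "N3" = 3, "S3" = 3, "3" = 3,
  "R" = 4, "REM" = 4, "5" = 4, "4" = 4)

#' Read a hypnogram annotation file
#'
#' One stage token per line. Accepted tokens (case-insensitive): AASM
#' labels `W, N1, N2, N3, R` (plus `WAKE`, `REM`, `S1..S3`) and numeric
#' codes `0..5` where both 4 and 5 decode to R (ISRUC exports use 5).
#'
#' @param path Path to the annotation file.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tok <- trimws(readLines(path))
  keep <- nzchar(tok)
  tok <- toupper(tok[keep])
  if (length(tok) == 0L) stop("empty hypnogram file: ", path)
  code <- .stage_aliases[tok]
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("unknown stage token '", tok[bad], "' at line ",
         which(keep)[bad], " of ", path)
  }
  hypnogram(unname(code))
}

#' Write a hypnogram annotation file
#'
#' One canonical stage label (`W/N1/N2/N3/R`) per line; the exact inverse
#' of [read_hypnogram()].
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  writeLines(stage_names(h), path)
  invisible(path)
}

#' Epochs on which two scorers agree
#'
#' Only consensus epochs — those labeled identically by both scorers — are
#' kept for training and evaluation, which removes ambiguous epochs.
#'
#' @param h1,h2 Two [hypnogram()]s of equal length.
#' @return Sorted integer vector of 1-based epoch indices where the two
#'   hypnograms agree.
#' @export
consensus_filter <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("hypnogram lengths differ: ", length(h1), " vs ", length(h2))
  which(as.integer(h1) == as.integer(h2))
}
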