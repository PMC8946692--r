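# Orchestration: prepare datasets (spectrogram or raw mode), train,
# predict and evaluate, driven by a single config; every step writes a
# manifest with the config, seed and outputs so runs are reproducible.

#' Pipeline configuration
#'
#' One structure drives every stage of the pipeline. Defaults equal the
#' standard processing parameters throughout (0.3-35 Hz band-pass, 50 Hz
#' notch, 5 s / 1 s multitaper windows with NW = 5 and 9 tapers, 0-20 Hz
#' band, 60/20/20 split).
#'
#' @param mode `"spectrogram"` (64x64x3 image CNN) or `"raw"` (6000x4
#'   CNN+LSTM).
#' @param filter A [filter_params()].
#' @param multitaper An [mt_params()].
#' @param model A [cnn_config()] or [cnn_lstm_config()]; defaults to the
#'   one matching `mode`.
#' @param schedule A [train_schedule()].
#' @param fractions Train/validation/test split fractions.
#' @param seed Run seed.
#' @param out_dir Output directory for prepared data, checkpoints and
#'   reports.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("spectrogram", "raw"),
                            filter = filter_params(),
                            multitaper = mt_params(),
                            model = NULL,
                            schedule = train_schedule(),
                            fractions = c(0.6, 0.2, 0.2),
                            seed = 1L,
                            out_dir = tempfile("somnostage_")) {
  mode <- match.arg(mode)
  if (is.null(model))
    model <- if (mode == "spectrogram") cnn_config() else cnn_lstm_config()
  structure(list(mode = mode, filter = filter, multitaper = multitaper,
                 model = model, schedule = schedule, fractions = fractions,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Only keys present in the file override the defaults; nested sections
#' (`filter`, `multitaper`, `model`, `schedule`) merge key-by-key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- pipeline_config(mode = if (is.null(raw$mode)) "spectrogram"
                         else raw$mode)
  for (sec in c("filter", "multitaper", "model", "schedule"))
    if (!is.null(raw[[sec]]))
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
  for (k in c("fractions", "seed", "out_dir"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  cfg
}

.write_manifest <- function(cfg, dir, extra = list()) {
  man <- c(list(mode = cfg$mode, seed = cfg$seed,
                filter = unclass(cfg$filter),
                multitaper = unclass(cfg$multitaper),
                schedule = unclass(cfg$schedule),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Prepare a labeled dataset from a recording
#'
#' Preprocesses the recording (notch, band-pass, resampling to 200 Hz),
#' aligns labels (with two-scorer consensus filtering if a second
#' hypnogram is given), and builds per-epoch model inputs in the
#' configured mode. Spectrogram mode writes one PNG per epoch plus a
#' label sidecar TSV; both modes store the model-input array and labels
#' in `<out_dir>/dataset.rds`. Epochs containing non-finite samples are
#' dropped with a warning.
#'
#' @param cfg A [pipeline_config()].
#' @param rec A [recording()] or path to an EDF file.
#' @param hyp A [hypnogram()] or path to an annotation file; optional.
#' @param hyp2 Second scorer's hypnogram (or path) for consensus
#'   filtering; optional.
#' @param channels Channels to select when `rec` is an EDF path.
#' @param recording_id Stem used in per-epoch PNG file names.
#' @return Invisibly, a list with `inputs`, `labels` (may be NULL),
#'   `kept_epochs` (indices into the original epoch sequence) and
#'   `out_dir`.
#' @export
run_prepare <- function(cfg, rec, hyp = NULL, hyp2 = NULL,
                        channels = NULL, recording_id = "rec") {
  if (is.character(rec)) rec <- read_edf(rec, channels)
  if (is.character(hyp)) hyp <- read_hypnogram(hyp)
  if (is.character(hyp2)) hyp2 <- read_hypnogram(hyp2)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # flag epochs with non-finite samples on the raw recording (IIR
  # filters cannot cross NAs); zero-fill the bad samples so filtering
  # proceeds, then drop the flagged epochs after preprocessing
  spe <- 30 * rec$fs
  n_ep_raw <- floor(nrow(rec$data) / spe)
  bad <- vapply(seq_len(n_ep_raw), function(e) {
    rows <- ((e - 1) * spe + 1):(e * spe)
    !all(is.finite(rec$data[rows, ]))
  }, TRUE)
  if (any(bad)) {
    warning(sum(bad), " epoch(s) contain non-finite samples and were dropped")
    rec$data[!is.finite(rec$data)] <- 0
  }

  rec <- preprocess_recording(rec, cfg$filter, target_fs = 200)
  n_ep <- floor(rec$duration_s / 30)
  keep <- which(!bad[seq_len(n_ep)])
  if (!is.null(hyp) && !is.null(hyp2)) {
    agree <- consensus_filter(hyp[seq_len(n_ep)], hyp2[seq_len(n_ep)])
    keep <- intersect(keep, agree)
  }

  if (cfg$mode == "spectrogram") {
    ei <- epoch_images(rec, cfg$multitaper, return_rasters = TRUE)
    inputs <- ei$inputs[, , , keep, drop = FALSE]
    png_dir <- file.path(cfg$out_dir, "epochs")
    dir.create(png_dir, showWarnings = FALSE)
    for (e in keep)
      write_epoch_png(ei$rasters[[e]],
                      file.path(png_dir, sprintf("%s_%05d.png",
                                                 recording_id, e)))
  } else {
    raw <- segment_raw_epochs(rec)
    inputs <- array(0, dim = c(6000, 4, length(keep)))
    for (i in seq_along(keep))
      inputs[, , i] <- t(raw[[keep[i]]]$samples)
  }

  labels <- if (!is.null(hyp)) hypnogram(as.integer(hyp)[keep]) else NULL
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(epoch_index = keep, stage = stage_names(labels)),
      file.path(cfg$out_dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- table(factor(stage_names(labels), levels = stage_levels()))
    message("prepared ", length(keep), " epochs (",
            paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  saveRDS(list(inputs = inputs, labels = labels, kept_epochs = keep,
               mode = cfg$mode), file.path(cfg$out_dir, "dataset.rds"))
  .write_manifest(cfg, cfg$out_dir,
                  list(n_epochs = length(keep), recording_id = recording_id))
  invisible(list(inputs = inputs, labels = labels, kept_epochs = keep,
                 out_dir = cfg$out_dir))
}

#' Train a classifier on a prepared dataset
#'
#' @param cfg A [pipeline_config()].
#' @param dataset Result of [run_prepare()] (or the path of its
#'   `out_dir`).
#' @param verbose Print per-epoch progress.
#' @return The fitted [fit_stagenet()] model; a checkpoint
#'   (`checkpoint.rds`), training curves (`curves.csv`) and a manifest
#'   are written to `cfg$out_dir`.
#' @export
run_train <- function(cfg, dataset, verbose = FALSE) {
  if (is.character(dataset))
    dataset <- readRDS(file.path(dataset, "dataset.rds"))
  if (is.null(dataset$labels))
    stop("training requires a labeled dataset")
  arch <- if (cfg$mode == "spectrogram") "cnn" else "cnn_lstm"
  fit <- fit_stagenet(dataset$inputs, dataset$labels, arch = arch,
                      config = cfg$model, schedule = cfg$schedule,
                      seed = cfg$seed, verbose = verbose)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(fit, file.path(cfg$out_dir, "checkpoint.rds"))
  utils::write.csv(fit$history, file.path(cfg$out_dir, "curves.csv"),
                   row.names = FALSE)
  .write_manifest(cfg, cfg$out_dir,
                  list(best_val_loss = fit$classifier$best_val_loss,
                       n_params = n_params(fit$classifier)))
  fit
}

#' Predict stages for a recording with a trained model
#'
#' Runs the full preprocessing + epoching chain in the model's mode
#' (recordings at 250 Hz are resampled to 200 Hz automatically), predicts
#' one stage per epoch, writes the predicted hypnogram, and — when
#' reference labels are given — an evaluation report.
#'
#' @param cfg A [pipeline_config()].
#' @param fit A fitted [fit_stagenet()] model, or the path to a
#'   `checkpoint.rds`.
#' @param rec A [recording()] or EDF path.
#' @param hyp Optional reference [hypnogram()] (or path) for evaluation.
#' @param channels Channels to select when `rec` is an EDF path.
#' @return List with `hypnogram` (predicted) and, if labels were given,
#'   `report` (an `eval_report`).
#' @export
run_predict <- function(cfg, fit, rec, hyp = NULL, channels = NULL) {
  if (is.character(fit)) fit <- readRDS(fit)
  want_arch <- if (cfg$mode == "spectrogram") "cnn" else "cnn_lstm"
  if (fit$arch != want_arch)
    stop("checkpoint architecture (", fit$arch,
         ") does not match pipeline mode (", cfg$mode, ")")
  if (is.character(rec)) rec <- read_edf(rec, channels)
  if (is.character(hyp)) hyp <- read_hypnogram(hyp)

  rec <- preprocess_recording(rec, cfg$filter, target_fs = 200)
  inputs <- if (cfg$mode == "spectrogram")
    epoch_images(rec, cfg$multitaper)$inputs
  else {
    raw <- segment_raw_epochs(rec)
    arr <- array(0, dim = c(6000, 4, length(raw)))
    for (i in seq_along(raw)) arr[, , i] <- t(raw[[i]]$samples)
    arr
  }
  pred <- predict(fit, inputs)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  export_hypnogram(pred, file.path(cfg$out_dir, "predicted_hypnogram"))
  out <- list(hypnogram = pred)
  if (!is.null(hyp)) {
    truth <- hyp[seq_len(length(pred))]
    out$report <- evaluate_predictions(pred, truth)
    rep <- out$report
    jsonlite::write_json(
      list(accuracy = rep$accuracy, kappa = rep$kappa,
           confusion = rep$confusion, n_epochs = rep$n_epochs,
           per_stage = as.list(rep$per_stage)),
      file.path(cfg$out_dir, "eval_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(rep$confusion,
                     file.path(cfg$out_dir, "confusion.csv"))
  }
  out
}
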