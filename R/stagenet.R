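# High-level modelling interface: one fitting function returning a
# classed object with the usual print/summary/predict/plot methods.

#' Fit a sleep-stage classifier
#'
#' The front door to the two classifiers: builds the requested
#' architecture, trains it with the annealing/early-stopping schedule and
#' returns a fitted model object.
#'
#' @param x Training inputs: `64 x 64 x 3 x n` spectrogram images
#'   (`arch = "cnn"`) or `6000 x 4 x n` raw epochs (`arch = "cnn_lstm"`).
#' @param y Stage labels: a [hypnogram()], integer codes 0..4 or stage
#'   names, length n.
#' @param arch `"cnn"` (spectrogram images) or `"cnn_lstm"` (raw
#'   signals).
#' @param config A [cnn_config()] or [cnn_lstm_config()] matching `arch`.
#' @param schedule A [train_schedule()].
#' @param seed Run seed for weight initialization, the validation split,
#'   shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return Object of class `stagenet` with the trained classifier,
#'   training `history`, `arch`, `seed` and the schedule used.
#' @export
fit_stagenet <- function(x, y, arch = c("cnn", "cnn_lstm"),
                         config = NULL, schedule = train_schedule(),
                         seed = 1L, verbose = FALSE) {
  arch <- match.arg(arch)
  set.seed(seed)
  clf <- if (arch == "cnn") {
    if (is.null(config)) config <- cnn_config()
    build_cnn(config)
  } else {
    if (is.null(config)) config <- cnn_lstm_config()
    build_cnn_lstm(config)
  }
  clf <- train_classifier(clf, x, y, schedule = schedule, seed = seed,
                          verbose = verbose)
  structure(list(classifier = clf, arch = arch, history = clf$history,
                 schedule = schedule, seed = seed,
                 n_train = dim(x)[length(dim(x))]),
            class = "stagenet")
}

#' @export
print.stagenet <- function(x, ...) {
  cat("Sleep-stage classifier (", x$arch, ")\n", sep = "")
  cat("  trained on ", x$n_train, " epochs, seed ", x$seed, "\n", sep = "")
  h <- x$history
  cat(sprintf(
    "  %d training epochs, best val loss %.4f (val acc %.3f), %d lr decay(s)\n",
    nrow(h), min(h$val_loss), h$val_acc[which.min(h$val_loss)],
    x$classifier$decays))
  invisible(x)
}

#' @export
summary.stagenet <- function(object, ...) {
  print(object)
  cat("  parameters:", format(n_params(object$classifier),
                              big.mark = ","), "\n")
  cat("  final lr:", object$classifier$lr_final, "\n")
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Predict sleep stages from a fitted model
#'
#' @param object A fitted [fit_stagenet()] model.
#' @param newdata Input array matching the architecture (batch last;
#'   the batch dimension may be omitted for a single epoch).
#' @param type `"class"` for a [hypnogram()] of labels, `"prob"` for the
#'   n x 5 probability matrix.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.stagenet <- function(object, newdata,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object$classifier, newdata)
  else predict_stages(object$classifier, newdata)
}

#' Plot training curves
#'
#' Loss (left axis) and accuracy (right panel) of the training and
#' validation sets over epochs.
#'
#' @param x A fitted [fit_stagenet()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stagenet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "red",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, col = "blue")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("red", "blue"), bty = "n")
  graphics::plot(h$epoch, h$train_acc, type = "l", col = "red",
                 xlab = "epoch", ylab = "accuracy", ylim = c(0, 1), ...)
  graphics::lines(h$epoch, h$val_acc, col = "blue")
  invisible(x)
}
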