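# Dataset splitting and agreement metrics: accuracy, unweighted Cohen's
# kappa, 5x5 confusion matrices and hypnogram export.

#' Random train/validation/test split of epoch indices
#'
#' Sizes are `floor(n * fraction)` for validation and test; the remainder
#' goes to training. The three sets are disjoint and exhaustive.
#'
#' @param n_epochs Total number of epochs.
#' @param fractions Length-3 fractions (train, validation, test) summing
#'   to 1.
#' @param seed RNG seed for the shuffle.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_epochs, fractions = c(0.6, 0.2, 0.2),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1, got ", sum(fractions))
  set.seed(seed)
  ord <- sample.int(n_epochs)
  n_val <- floor(n_epochs * fractions[2])
  n_test <- floor(n_epochs * fractions[3])
  n_train <- n_epochs - n_val - n_test
  list(train = sort(ord[seq_len(n_train)]),
       val = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[n_train + n_val + seq_len(n_test)]))
}

.as_stage_int <- function(x) {
  if (inherits(x, "hypnogram")) return(as.integer(x))
  if (is.character(x)) return(as.integer(hypnogram(x)))
  as.integer(x)
}

#' Classification accuracy
#'
#' @param pred,truth Two equal-length stage sequences ([hypnogram()]s,
#'   integer codes or stage names).
#' @return Fraction of agreeing epochs.
#' @export
stage_accuracy <- function(pred, truth) {
  p <- .as_stage_int(pred); t_ <- .as_stage_int(truth)
  if (length(p) != length(t_))
    stop("sequence lengths differ: ", length(p), " vs ", length(t_))
  if (length(p) == 0L) stop("empty label sequences")
  mean(p == t_)
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_e` is
#' the product-of-marginals chance agreement. If both sequences are
#' constant and identical (`p_e == 1`), kappa is defined as 1 and a
#' message is logged.
#'
#' @inheritParams stage_accuracy
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(pred, truth) {
  p <- .as_stage_int(pred); t_ <- .as_stage_int(truth)
  if (length(p) != length(t_))
    stop("sequence lengths differ: ", length(p), " vs ", length(t_))
  n <- length(p)
  if (n == 0L) stop("empty label sequences")
  lev <- sort(unique(c(p, t_)))
  tab <- table(factor(t_, levels = lev), factor(p, levels = lev))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    message("cohen_kappa: both raters constant and equal; kappa = 1 by ",
            "convention")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Five-stage confusion matrix
#'
#' Rows are the true stages, columns the predicted stages, both in the
#' fixed W, N1, N2, N3, R order.
#'
#' @inheritParams stage_accuracy
#' @return 5 x 5 integer matrix of counts.
#' @export
confusion_matrix <- function(pred, truth) {
  p <- .as_stage_int(pred); t_ <- .as_stage_int(truth)
  if (any(c(p, t_) < 0L | c(p, t_) > 4L))
    stop("stage codes out of range 0..4")
  m <- table(factor(t_, levels = 0:4), factor(p, levels = 0:4))
  m <- matrix(as.integer(m), 5, 5,
              dimnames = list(true = stage_levels(),
                              predicted = stage_levels()))
  m
}

#' Full evaluation report
#'
#' @inheritParams stage_accuracy
#' @return Object of class `eval_report`: `accuracy`, `kappa`,
#'   `confusion` (5x5), `n_epochs` and `per_stage` true-stage counts.
#' @export
evaluate_predictions <- function(pred, truth) {
  cm <- confusion_matrix(pred, truth)
  structure(list(accuracy = stage_accuracy(pred, truth),
                 kappa = cohen_kappa(pred, truth),
                 confusion = cm,
                 n_epochs = sum(cm),
                 per_stage = rowSums(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d epochs | accuracy %.2f%% | kappa %.3f\n",
              x$n_epochs, 100 * x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Export a hypnogram as TSV and a step-plot image
#'
#' Writes `<path>.tsv` with columns `epoch_index` (1-based) and `stage`,
#' and `<path>.png` with the conventional step plot (stage depth on a
#' reversed axis, R highlighted).
#'
#' @param h A [hypnogram()].
#' @param path Output path stem (extensions are appended).
#' @return Named character vector of the files written, invisibly.
#' @export
export_hypnogram <- function(h, path) {
  if (length(h) == 0L) stop("empty hypnogram")
  tsv <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(epoch_index = seq_along(h), stage = stage_names(h)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  img <- paste0(path, ".png")
  grDevices::png(img, width = 900, height = 300)
  on.exit(grDevices::dev.off())
  plot_order <- c(W = 4, R = 3, N1 = 2, N2 = 1, N3 = 0)
  yv <- plot_order[stage_names(h)]
  graphics::plot(seq_along(h) / 2, yv, type = "s", yaxt = "n",
                 xlab = "time (min)", ylab = "stage",
                 main = "Hypnogram", ylim = c(-0.2, 4.2))
  graphics::axis(2, at = plot_order, labels = names(plot_order), las = 1)
  invisible(c(tsv = tsv, png = img))
}

#' Read back a hypnogram TSV written by [export_hypnogram()]
#' @param path Path to the `.tsv` file.
#' @return A [hypnogram()].
#' @export
read_hypnogram_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character"))
  hypnogram(tab$stage[order(tab$epoch_index)])
}
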