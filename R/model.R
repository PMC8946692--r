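# The two sleep-stage classifiers and their training procedure.
#
# Spectrogram CNN: three conv cells (conv -> batch norm -> 2x2 max pool
# -> Leaky ReLU) with 64/64/32 filters and 3x3 kernels on a 64x64x3
# input, then dense 1024 -> dropout 0.25 -> dense 512 -> dropout 0.40 ->
# dense 5 and softmax. Raw-signal CNN+LSTM: two 1D conv cells (80
# filters kernel 3, then 32 filters kernel 5, each with pool size 4) on
# a 6000x4 input, an LSTM with 10 units (last output), dense 64 ->
# dropout 0.45 -> dense 5 and softmax. Training uses Adam with
# learning-rate annealing by a factor of 5 on validation-loss plateaus
# and stops after two successive decays without improvement.

#' Configuration of the spectrogram-image CNN
#'
#' @param conv_filters Filter counts of the three conv cells.
#' @param conv_kernel Square kernel size.
#' @param dense_units Units of the three dense layers (last must be 5).
#' @param dropout The two dropout rates after the first two dense layers.
#' @param leaky_slope Negative-region slope of the Leaky ReLU.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(conv_filters = c(64, 64, 32), conv_kernel = 3,
                       dense_units = c(1024, 512, 5),
                       dropout = c(0.25, 0.40), leaky_slope = 0.01,
                       lr = 0.002, batch_size = 16) {
  if (dense_units[length(dense_units)] != 5)
    stop("the final dense layer must have 5 units (five sleep stages)")
  if (any(dropout <= 0 | dropout >= 1)) stop("dropout rates must be in (0,1)")
  structure(list(conv_filters = conv_filters, conv_kernel = conv_kernel,
                 dense_units = dense_units, dropout = dropout,
                 leaky_slope = leaky_slope, lr = lr,
                 batch_size = batch_size),
            class = "cnn_config")
}

#' Configuration of the raw-signal CNN+LSTM
#'
#' @param conv1_filters,conv1_kernel First 1D conv cell (80 filters,
#'   kernel 3).
#' @param conv2_filters,conv2_kernel Second 1D conv cell (32 filters,
#'   kernel 5).
#' @param pool 1D max-pool size applied in both cells.
#' @param lstm_units LSTM hidden units.
#' @param dense_units Units of the two dense layers (last must be 5).
#' @param dropout Dropout rate before the output layer.
#' @param leaky_slope Negative-region slope of the Leaky ReLU.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @return List of class `cnn_lstm_config`.
#' @export
cnn_lstm_config <- function(conv1_filters = 80, conv1_kernel = 3,
                            conv2_filters = 32, conv2_kernel = 5,
                            pool = 4, lstm_units = 10,
                            dense_units = c(64, 5), dropout = 0.45,
                            leaky_slope = 0.01, lr = 0.001,
                            batch_size = 128) {
  if (dense_units[length(dense_units)] != 5)
    stop("the final dense layer must have 5 units (five sleep stages)")
  structure(list(conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
                 conv2_filters = conv2_filters, conv2_kernel = conv2_kernel,
                 pool = pool, lstm_units = lstm_units,
                 dense_units = dense_units, dropout = dropout,
                 leaky_slope = leaky_slope, lr = lr,
                 batch_size = batch_size),
            class = "cnn_lstm_config")
}

#' Training schedule
#'
#' Early stopping with learning-rate annealing: when the validation loss
#' has not improved for `patience` epochs the learning rate is divided by
#' `anneal_factor`; training stops after `max_decays` successive decays
#' with no improvement in between. 20% of the training data, sampled once
#' at the start of the run, serves as the validation set.
#'
#' @param anneal_factor Learning-rate division factor per decay.
#' @param max_decays Number of successive no-improvement decays that
#'   terminates training.
#' @param patience Epochs without validation-loss improvement before each
#'   decay.
#' @param val_fraction Fraction of the training set held out for
#'   validation.
#' @param max_epochs Hard cap on training epochs.
#' @return List of class `train_schedule`.
#' @export
train_schedule <- function(anneal_factor = 5, max_decays = 2, patience = 5,
                           val_fraction = 0.2, max_epochs = 50) {
  if (anneal_factor <= 1) stop("anneal_factor must exceed 1")
  if (max_decays < 1) stop("max_decays must be at least 1")
  structure(list(anneal_factor = anneal_factor, max_decays = max_decays,
                 patience = patience, val_fraction = val_fraction,
                 max_epochs = max_epochs),
            class = "train_schedule")
}

#' Annealing state machine
#'
#' The plateau/decay/termination logic of [train_schedule()], exposed as
#' a pure state machine: feed one validation loss per epoch with
#' [anneal_step()] and read `lr`, `decays` and `stop`.
#'
#' @param lr0 Initial learning rate.
#' @param schedule A [train_schedule()].
#' @return State list with fields `lr`, `decays`, `stop`, `best_loss`,
#'   `best_is_current`, `wait`.
#' @export
anneal_init <- function(lr0, schedule = train_schedule()) {
  list(lr0 = lr0, lr = lr0, decays = 0L, wait = 0L, stop = FALSE,
       best_loss = Inf, best_is_current = FALSE,
       improved_since_decay = TRUE, schedule = schedule)
}

#' @rdname anneal_init
#' @param state State from [anneal_init()] or a previous [anneal_step()].
#' @param val_loss Validation loss of the epoch just finished.
#' @export
anneal_step <- function(state, val_loss) {
  sc <- state$schedule
  if (val_loss < state$best_loss - 1e-12) {
    state$best_loss <- val_loss
    state$best_is_current <- TRUE
    state$wait <- 0L
    state$improved_since_decay <- TRUE
  } else {
    state$best_is_current <- FALSE
    state$wait <- state$wait + 1L
    if (state$wait >= sc$patience) {
      if (state$decays >= sc$max_decays) {
        state$stop <- TRUE
      } else {
        state$decays <- state$decays + 1L
        state$lr <- state$lr0 / sc$anneal_factor^state$decays
        state$wait <- 0L
        if (!state$improved_since_decay && state$decays >= sc$max_decays)
          state$stop <- TRUE
        if (state$decays == 1L) state$improved_since_decay <- FALSE
      }
    }
  }
  state
}

# assemble the layer stack for one architecture
.cnn_layers <- function(cfg) {
  k <- cfg$conv_kernel
  lys <- list()
  c_in <- 3L
  for (f in cfg$conv_filters) {
    lys <- c(lys, list(.layer_conv2d(c_in, f, k), .layer_bn(f),
                       .layer_pool2(), .layer_lrelu(cfg$leaky_slope)))
    c_in <- f
  }
  side <- 64L / 2L^length(cfg$conv_filters)
  flat <- side * side * c_in
  lys <- c(lys, list(.layer_flatten(),
                     .layer_dense(flat, cfg$dense_units[1]),
                     .layer_lrelu(cfg$leaky_slope),
                     .layer_dropout(cfg$dropout[1]),
                     .layer_dense(cfg$dense_units[1], cfg$dense_units[2]),
                     .layer_lrelu(cfg$leaky_slope),
                     .layer_dropout(cfg$dropout[2]),
                     .layer_dense(cfg$dense_units[2], cfg$dense_units[3])))
  lys
}

.cnn_lstm_layers <- function(cfg) {
  seq_len1 <- 6000L %/% cfg$pool
  seq_len2 <- seq_len1 %/% cfg$pool
  lys <- list(
    .layer_conv1d(4L, cfg$conv1_filters, cfg$conv1_kernel),
    .layer_bn(cfg$conv1_filters), .layer_pool1(cfg$pool),
    .layer_lrelu(cfg$leaky_slope),
    .layer_conv1d(cfg$conv1_filters, cfg$conv2_filters, cfg$conv2_kernel),
    .layer_bn(cfg$conv2_filters), .layer_pool1(cfg$pool),
    .layer_lrelu(cfg$leaky_slope),
    .layer_lstm(cfg$conv2_filters, cfg$lstm_units),
    .layer_dense(cfg$lstm_units, cfg$dense_units[1]),
    .layer_lrelu(cfg$leaky_slope),
    .layer_dropout(cfg$dropout),
    .layer_dense(cfg$dense_units[1], cfg$dense_units[2]))
  attr(lys, "seq_len_after_pools") <- seq_len2
  lys
}

#' Build the spectrogram-image CNN
#'
#' Maps a 64 x 64 x 3 normalized spectrogram image to 5 softmax class
#' probabilities. Weights are drawn from the current RNG; call
#' `set.seed()` first for reproducible initialization.
#'
#' @param cfg A [cnn_config()].
#' @return A `stage_classifier` object (architecture `"cnn"`).
#' @export
build_cnn <- function(cfg = cnn_config()) {
  lys <- .cnn_layers(cfg)
  structure(list(layers = lys, arch = "cnn", cfg = cfg,
                 input_dim = c(64L, 64L, 3L),
                 n_params = .net_n_params(lys)),
            class = "stage_classifier")
}

#' Build the raw-signal CNN+LSTM
#'
#' Maps a 30 s raw epoch (6000 samples x 4 channels) to 5 softmax class
#' probabilities.
#'
#' @param cfg A [cnn_lstm_config()].
#' @return A `stage_classifier` object (architecture `"cnn_lstm"`); its
#'   `seq_len` field is the sequence length entering the LSTM after the
#'   two pooling stages.
#' @export
build_cnn_lstm <- function(cfg = cnn_lstm_config()) {
  lys <- .cnn_lstm_layers(cfg)
  structure(list(layers = lys, arch = "cnn_lstm", cfg = cfg,
                 input_dim = c(6000L, 4L),
                 seq_len = attr(lys, "seq_len_after_pools"),
                 n_params = .net_n_params(lys)),
            class = "stage_classifier")
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat("<stage_classifier> ", x$arch, ": input ",
      paste(x$input_dim, collapse = " x "), " -> 5 classes, ",
      format(x$n_params, big.mark = ","), " trainable parameters\n",
      sep = "")
  invisible(x)
}

# check/convert input batch for a classifier; returns [.., B] array
.check_inputs <- function(clf, x) {
  d <- dim(x)
  nd <- length(clf$input_dim)
  if (length(d) == nd) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  if (length(d) != nd + 1L || !all(d[seq_len(nd)] == clf$input_dim))
    stop("input shape ", paste(d, collapse = " x "),
         " does not match the model's expected ",
         paste(clf$input_dim, collapse = " x "), " (x batch)")
  x
}

#' Class probabilities for a batch of inputs
#'
#' @param clf A `stage_classifier`.
#' @param x Input array: `64 x 64 x 3 x B` (cnn) or `6000 x 4 x B`
#'   (cnn_lstm); the batch dimension may be omitted for one input.
#' @param batch_size Forward-pass chunk size.
#' @return A `B x 5` matrix of softmax probabilities (columns W,N1,N2,N3,R).
#' @export
predict_proba <- function(clf, x, batch_size = 64) {
  x <- .to_cf(.check_inputs(clf, x))
  nd <- length(dim(x))
  B <- dim(x)[nd]
  out <- matrix(0, B, 5)
  idx_all <- seq_len(B)
  for (lo in seq(1L, B, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, B)
    xb <- if (nd == 4L) x[, , , lo:hi, drop = FALSE]
          else x[, , lo:hi, drop = FALSE]
    logits <- .net_forward(clf$layers, xb, train = FALSE)
    out[lo:hi, ] <- t(.softmax(logits))
  }
  colnames(out) <- stage_levels()
  out
}

#' Predict stage labels
#'
#' Argmax of the class probabilities; exact ties resolve to the lowest
#' stage index (W first).
#'
#' @inheritParams predict_proba
#' @return A [hypnogram()] of predicted stages (codes 0..4).
#' @export
predict_stages <- function(clf, x, batch_size = 64) {
  p <- predict_proba(clf, x, batch_size)
  hypnogram(max.col(p, ties.method = "first") - 1L)
}

#' Train a classifier
#'
#' Minibatch Adam with the annealing/early-stopping schedule. A
#' `val_fraction` share of the data is sampled once at the start as the
#' validation set; the returned model carries the parameters of the best
#' validation-loss epoch.
#'
#' @param clf A `stage_classifier` from [build_cnn()] or
#'   [build_cnn_lstm()].
#' @param x Input array (batch last).
#' @param y Stage labels: a [hypnogram()], integer codes 0..4, or stage
#'   names.
#' @param schedule A [train_schedule()].
#' @param seed Run seed controlling weight shuffling, dropout and the
#'   validation split.
#' @param verbose Print one line per epoch.
#' @return The trained `stage_classifier` with a `history` data frame
#'   (epoch, train_loss, val_loss, train_acc, val_acc, lr), `decays`,
#'   `seed` and `best_val_loss` fields.
#' @export
train_classifier <- function(clf, x, y, schedule = train_schedule(),
                             seed = 1L, verbose = FALSE) {
  x <- .to_cf(.check_inputs(clf, x))
  if (inherits(y, "hypnogram") || is.character(y)) y <- hypnogram(y)
  y <- as.integer(y) + 1L                 # 1..5 class index
  nd <- length(dim(x))
  B_all <- dim(x)[nd]
  if (length(y) != B_all)
    stop("label count (", length(y), ") does not match input batch (",
         B_all, ")")
  if (length(unique(y)) < 2L)
    stop("training data contain a single class; at least two are required")

  set.seed(seed)
  n_val <- max(1L, round(schedule$val_fraction * B_all))
  val_idx <- sort(sample.int(B_all, n_val))
  tr_idx <- setdiff(seq_len(B_all), val_idx)
  take <- function(i) if (nd == 4L) x[, , , i, drop = FALSE]
                      else x[, , i, drop = FALSE]

  bs <- clf$cfg$batch_size
  st <- anneal_init(clf$cfg$lr, schedule)
  hist_rows <- list()
  best_params <- NULL; best_val <- Inf

  eval_set <- function(idx) {
    tot_l <- 0; tot_a <- 0
    for (lo in seq(1L, length(idx), by = 64L)) {
      hi <- min(lo + 63L, length(idx))
      ii <- idx[lo:hi]
      lg <- .net_forward(clf$layers, take(ii), train = FALSE)
      r <- .xent_loss_grad(lg, y[ii])
      tot_l <- tot_l + r$loss * length(ii)
      tot_a <- tot_a + r$acc * length(ii)
    }
    c(tot_l, tot_a) / length(idx)
  }

  for (ep in seq_len(schedule$max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_acc <- 0
    for (lo in seq(1L, length(ord), by = bs)) {
      hi <- min(lo + bs - 1L, length(ord))
      ii <- ord[lo:hi]
      logits <- .net_forward(clf$layers, take(ii), train = TRUE)
      r <- .xent_loss_grad(logits, y[ii])
      .net_backward(clf$layers, r$dlogits)
      .adam_step(clf$layers, st$lr)
      ep_loss <- ep_loss + r$loss * length(ii)
      ep_acc <- ep_acc + r$acc * length(ii)
    }
    ep_loss <- ep_loss / length(ord); ep_acc <- ep_acc / length(ord)
    v <- eval_set(val_idx)
    st <- anneal_step(st, v[1])
    if (v[1] < best_val) {
      best_val <- v[1]
      best_params <- .net_param_list(clf$layers)
    }
    hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss,
                                  val_loss = v[1], train_acc = ep_acc,
                                  val_acc = v[2], lr = st$lr)
    if (verbose)
      message(sprintf(
        "epoch %3d  train %.4f/%.3f  val %.4f/%.3f  lr %.2e  decays %d",
        ep, ep_loss, ep_acc, v[1], v[2], st$lr, st$decays))
    if (st$stop) break
  }

  if (!is.null(best_params)) .net_set_params(clf$layers, best_params)
  clf$history <- do.call(rbind, hist_rows)
  clf$decays <- st$decays
  clf$lr_final <- st$lr
  clf$best_val_loss <- best_val
  clf$seed <- seed
  clf$trained <- TRUE
  clf
}

#' Number of trainable parameters
#' @param clf A `stage_classifier`.
#' @return Integer count of trainable parameters (conv/dense weights and
#'   biases, batch-norm scale and shift, LSTM matrices).
#' @export
n_params <- function(clf) .net_n_params(clf$layers)
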