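# Classifier construction, forward-pass contracts, analytic gradients
# against numerical differentiation, the annealing schedule, and
# learning on a separable toy problem with a logistic-regression oracle.

test_that("the CNN maps images to a 5-class probability simplex", {
  set.seed(51)
  clf <- build_cnn()
  p <- predict_proba(clf, array(0, c(64, 64, 3)))
  expect_equal(dim(p), c(1, 5))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  batch <- array(stats::runif(64 * 64 * 3 * 7), c(64, 64, 3, 7))
  pb <- predict_proba(clf, batch)
  expect_equal(nrow(pb), 7)
  expect_equal(rowSums(pb), rep(1, 7), tolerance = 1e-6)
  # order preserved: single-input forward equals its batch row
  p3 <- predict_proba(clf, batch[, , , 3])
  expect_equal(unname(p3[1, ]), unname(pb[3, ]), tolerance = 1e-10)

  expect_error(predict_proba(clf, array(0, c(32, 32, 3))), "shape")
})

test_that("CNN parameter count matches the closed-form layer sum", {
  clf <- build_cnn()
  # conv cells: weights c_out*(c_in*3*3)+c_out, batch norm 2*c_out
  conv <- (64 * 3 * 9 + 64 + 128) + (64 * 64 * 9 + 64 + 128) +
    (32 * 64 * 9 + 32 + 64)
  # dense head on the 8*8*32 = 2048 flattened features
  dense <- (2048 * 1024 + 1024) + (1024 * 512 + 512) + (512 * 5 + 5)
  expect_equal(n_params(clf), conv + dense)
})

test_that("the CNN+LSTM accepts 6000x4 epochs and pools to length 375", {
  set.seed(52)
  clf <- build_cnn_lstm()
  expect_equal(clf$seq_len, floor(floor(6000 / 4) / 4))

  p <- predict_proba(clf, array(0, c(6000, 4)))
  expect_equal(dim(p), c(1, 5))
  expect_equal(sum(p), 1, tolerance = 1e-6)

  expect_error(predict_proba(clf, array(0, c(6000, 2))), "shape")
})

test_that("stage prediction is argmax with ties toward W", {
  set.seed(53)
  clf <- build_cnn()
  # zero out the output layer: all-equal probabilities, tie -> W
  out_layer <- clf$layers[[length(clf$layers)]]
  out_layer$W[] <- 0; out_layer$b[] <- 0
  pred <- predict_stages(clf, array(stats::runif(64 * 64 * 3 * 3),
                                    c(64, 64, 3, 3)))
  expect_equal(as.integer(pred), c(0L, 0L, 0L))

  # one-hot logit at stage index 4 (N3)
  out_layer$b[] <- c(0, 0, 0, 50, 0)
  pred2 <- predict_stages(clf, array(0, c(64, 64, 3, 2)))
  expect_equal(as.integer(pred2), c(3L, 3L))
})

test_that("layer gradients agree with numerical differentiation", {
  set.seed(54)
  nets <- list(
    cnn2d = list(
      layers = list(somnostage:::.layer_conv2d(2, 3, 3),
                    somnostage:::.layer_bn(3),
                    somnostage:::.layer_pool2(),
                    somnostage:::.layer_lrelu(0.01),
                    somnostage:::.layer_flatten(),
                    somnostage:::.layer_dense(3 * 4 * 4, 7),
                    somnostage:::.layer_lrelu(0.01),
                    somnostage:::.layer_dense(7, 5)),
      x = array(stats::rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))),
    cnn1d_lstm = list(
      layers = list(somnostage:::.layer_conv1d(2, 4, 3),
                    somnostage:::.layer_bn(4),
                    somnostage:::.layer_pool1(2),
                    somnostage:::.layer_lrelu(0.01),
                    somnostage:::.layer_conv1d(4, 3, 5),
                    somnostage:::.layer_pool1(2),
                    somnostage:::.layer_lstm(3, 4),
                    somnostage:::.layer_dense(4, 5)),
      x = array(stats::rnorm(2 * 16 * 3), c(2, 16, 3))))
  y <- c(1, 3, 5)
  for (net in nets) {
    layers <- net$layers
    loss_at <- function() {
      lg <- somnostage:::.net_forward(layers, net$x, train = TRUE)
      somnostage:::.xent_loss_grad(lg, y)$loss
    }
    for (ly in layers) {
      for (p in somnostage:::.param_names(ly)) {
        pv <- get(p, envir = ly)
        for (i in sample(length(pv), min(4, length(pv)))) {
          fn <- function(v) {
            pv2 <- pv; pv2[i] <- v
            assign(p, pv2, envir = ly)
            on.exit(assign(p, pv, envir = ly))
            loss_at()
          }
          ng <- (fn(pv[i] + 1e-5) - fn(pv[i] - 1e-5)) / 2e-5
          lg <- somnostage:::.net_forward(layers, net$x, train = TRUE)
          r <- somnostage:::.xent_loss_grad(lg, y)
          somnostage:::.net_backward(layers, r$dlogits)
          ag <- get("grads", envir = ly)[[p]][i]
          expect_lt(abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)), 1e-4)
        }
      }
    }
  }
})

test_that("the annealing machine decays twice by 5 then terminates", {
  sched <- train_schedule(patience = 3, max_epochs = 100)
  st <- anneal_init(0.002, sched)
  lrs <- decs <- c()
  for (ep in 1:50) {
    st <- anneal_step(st, 1.0)            # flat validation loss
    lrs <- c(lrs, st$lr); decs <- c(decs, st$decays)
    if (st$stop) break
  }
  expect_equal(st$decays, 2L)
  expect_true(st$stop)
  expect_equal(sort(unique(lrs)), sort(c(0.002, 0.002 / 5, 0.002 / 25)))
  expect_equal(st$lr, 0.002 / 25)
  expect_equal(ep, 1 + 2 * 3)             # improvement from Inf, 2x patience

  # an improvement resets the plateau counter
  st2 <- anneal_init(0.1, sched)
  st2 <- anneal_step(st2, 1.0)
  st2 <- anneal_step(st2, 1.0)
  st2 <- anneal_step(st2, 0.5)            # improves
  st2 <- anneal_step(st2, 0.6)
  st2 <- anneal_step(st2, 0.6)
  expect_equal(st2$decays, 0L)
  expect_equal(st2$lr, 0.1)
})

test_that("training is deterministic and rejects single-class data", {
  set.seed(55)
  x <- array(stats::runif(64 * 64 * 3 * 16), c(64, 64, 3, 16))
  y <- rep(0:1, 8)
  sched <- train_schedule(patience = 2, max_epochs = 2)
  f1 <- fit_stagenet(x, y, "cnn", schedule = sched, seed = 99)
  f2 <- fit_stagenet(x, y, "cnn", schedule = sched, seed = 99)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  # lr always equals lr0 / 5^decays
  expect_equal(f1$classifier$lr_final,
               0.002 / 5^f1$classifier$decays)

  expect_error(fit_stagenet(x, rep(2, 16), "cnn", schedule = sched),
               "single class")
})

test_that("the CNN fits linearly separable two-class images perfectly", {
  set.seed(56)
  n <- 64
  y <- rep(0:1, each = n / 2)
  x <- array(stats::runif(64 * 64 * 3 * n, 0, 0.2), c(64, 64, 3, n))
  x[, , , y == 1] <- x[, , , y == 1] + 0.6   # bright vs dark images

  # logistic-regression oracle on the mean-intensity feature: separable
  feat <- apply(x, 4, mean)
  glm_fit <- stats::glm(y ~ feat, family = stats::binomial)
  expect_equal(mean((stats::fitted(glm_fit) > 0.5) == y), 1)

  fit <- fit_stagenet(x, y, "cnn",
                      schedule = train_schedule(patience = 2,
                                                max_epochs = 10),
                      seed = 56)
  expect_equal(utils::tail(fit$history$train_acc, 1), 1)
  pred <- predict(fit, x)
  expect_equal(stage_accuracy(pred, y), 1)
})

test_that("a small CNN+LSTM run completes and learns amplitude classes", {
  set.seed(57)
  n <- 24
  y <- rep(0:1, each = n / 2)
  x <- array(stats::rnorm(6000 * 4 * n, sd = 5), c(6000, 4, n))
  x[, , y == 1] <- x[, , y == 1] * 8       # high- vs low-variance epochs
  cfg <- cnn_lstm_config(batch_size = 12)
  fit <- fit_stagenet(x, y, "cnn_lstm", config = cfg,
                      schedule = train_schedule(patience = 1,
                                                max_epochs = 4),
                      seed = 57)
  expect_s3_class(fit, "stagenet")
  expect_equal(length(predict(fit, x)), n)
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.5)
})
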