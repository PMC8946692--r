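# Splitting and agreement metrics. Kappa is checked against a
# hand-evaluated closed form and against an independent implementation.

test_that("splits are disjoint, exhaustive and deterministic", {
  sp <- split_dataset(100, seed = 5)
  expect_equal(lengths(sp), c(train = 60L, val = 20L, test = 20L))
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_identical(sp, split_dataset(100, seed = 5))

  sp101 <- split_dataset(101, seed = 5)   # remainder goes to training
  expect_equal(lengths(sp101), c(train = 61L, val = 20L, test = 20L))

  expect_error(split_dataset(10, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("accuracy counts exact matches", {
  expect_equal(stage_accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(stage_accuracy(c(0, 1, 2), c(1, 2, 3)), 0)
  expect_equal(stage_accuracy(c(0, 0, 0, 1, 1, 1), c(0, 0, 2, 2, 2, 1)),
               0.5)
  expect_error(stage_accuracy(integer(0), integer(0)), "empty")
  expect_error(stage_accuracy(c(0, 1), c(0, 1, 2)), "differ")
})

test_that("kappa reproduces the closed form on the worked example", {
  # true = A A A B B B, pred = A A B A B B: p_o = 2/3, p_e = 1/2,
  # kappa = (2/3 - 1/2) / (1 - 1/2) = 1/3
  truth <- c(0, 0, 0, 1, 1, 1)
  pred <- c(0, 0, 1, 0, 1, 1)
  expect_equal(cohen_kappa(pred, truth), 1 / 3, tolerance = 1e-12)

  expect_equal(cohen_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), 1)
  expect_message(k <- cohen_kappa(c(2, 2, 2), c(2, 2, 2)), "convention")
  expect_equal(k, 1)
})

test_that("kappa vanishes under independence and matches e1071", {
  set.seed(6)
  n <- 10000
  a <- sample(0:4, n, replace = TRUE)
  b <- sample(0:4, n, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)

  skip_if_not_installed("e1071")
  for (r in 1:5) {
    p <- sample(0:4, 500, replace = TRUE)
    t_ <- ifelse(stats::runif(500) < 0.6, p, sample(0:4, 500, TRUE))
    tab <- table(factor(t_, levels = 0:4), factor(p, levels = 0:4))
    expect_equal(cohen_kappa(p, t_),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
  }
})

test_that("confusion matrices count in fixed W..R order", {
  cm <- confusion_matrix(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_equal(rownames(cm), stage_levels())

  # worked kappa example embeds [[2,1],[1,2]] in the W/N1 block
  cm2 <- confusion_matrix(c(0, 0, 1, 0, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(cm2[1:2, 1:2]), matrix(c(2, 1, 1, 2), 2))
  expect_equal(sum(cm2), 6)

  expect_error(confusion_matrix(c(0, 7), c(0, 1)), "out of range")
})

test_that("metrics are mutually consistent on random data", {
  set.seed(7)
  for (r in 1:10) {
    p <- sample(0:4, 200, replace = TRUE)
    t_ <- sample(0:4, 200, replace = TRUE)
    cm <- confusion_matrix(p, t_)
    expect_equal(stage_accuracy(p, t_), sum(diag(cm)) / sum(cm))
  }
  # kappa == 1 iff the confusion matrix is diagonal (>= 2 classes)
  p <- c(0, 0, 1, 1, 2)
  expect_equal(cohen_kappa(p, p), 1)
  expect_lt(cohen_kappa(c(0, 0, 1, 1, 2), c(0, 0, 1, 2, 2)), 1)
})

test_that("evaluation reports aggregate all metrics", {
  set.seed(8)
  p <- sample(0:4, 100, replace = TRUE)
  t_ <- sample(0:4, 100, replace = TRUE)
  rep_ <- evaluate_predictions(p, t_)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n_epochs, 100)
  expect_equal(sum(rep_$confusion), 100)
  expect_equal(unname(rep_$per_stage),
               unname(as.integer(table(factor(t_, levels = 0:4)))))
  expect_output(print(rep_), "accuracy")
})

test_that("hypnogram export round-trips through the TSV sidecar", {
  h <- hypnogram(c(0, 1, 2, 3, 4, 2, 2, 1, 0, 4))
  stem <- tempfile()
  files <- export_hypnogram(h, stem)
  expect_true(all(file.exists(files)))
  tab <- utils::read.table(files["tsv"], header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 10)
  expect_identical(as.integer(read_hypnogram_tsv(files["tsv"])),
                   as.integer(h))
  empty <- structure(integer(0), class = "hypnogram")
  expect_error(export_hypnogram(empty, tempfile()), "empty")
})
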