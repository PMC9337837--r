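test_that("accuracy and individual accuracy follow the confusion matrix", {
  conf <- matrix(c(50, 20, 10, 20), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(accuracy(conf), 0.7)
  expect_identical(accuracy(diag(c(3, 4, 5))), 1.0)
  expect_identical(accuracy(matrix(c(0, 2, 3, 0), 2)), 0.0)
  expect_identical(individual_accuracy(conf, "A"), 50 / 70)
  row <- matrix(c(19, 1, 0, 0), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(individual_accuracy(row, "A"), 0.95)
  expect_true(is.na(individual_accuracy(row)[["B"]]))   # empty class
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("multiclass MCC handles perfect, constant and degenerate input", {
  y <- rep(c("A", "B", "C"), each = 5)
  expect_equal(mcc_multiclass(y, y), 1.0)
  expect_identical(mcc_multiclass(y, rep("A", 15)), 0)
  expect_error(mcc_multiclass(y, y[-1]), "equal length")
})

test_that("covariance-form MCC equals the closed-form RK statistic", {
  for (seed in 1:200) {
    withr::with_seed(seed, {
      n <- sample(10:60, 1)
      y <- sample(c("A", "B", "C"), n, replace = TRUE)
      p <- sample(c("A", "B", "C"), n, replace = TRUE)
    })
    expect_equal(mcc_multiclass(y, p),
                 oracle_rk(confusion_matrix(y, p)), tolerance = 1e-12)
  }
})

test_that("two-class MCC equals the classical binary formula", {
  for (seed in 1:200) {
    withr::with_seed(seed, {
      n <- sample(10:50, 1)
      y <- sample(c("pos", "neg"), n, replace = TRUE)
      p <- sample(c("pos", "neg"), n, replace = TRUE)
    })
    conf <- confusion_matrix(y, p, classes = c("pos", "neg"))
    expect_equal(mcc_multiclass(y, p),
                 oracle_binary_mcc(tp = conf["pos", "pos"],
                                   fn = conf["pos", "neg"],
                                   fp = conf["neg", "pos"],
                                   tn = conf["neg", "neg"]),
                 tolerance = 1e-12)
  }
})

test_that("MCC is invariant under class relabeling", {
  withr::with_seed(5, {
    y <- sample(c("A", "B", "C"), 60, replace = TRUE)
    p <- sample(c("A", "B", "C"), 60, replace = TRUE)
  })
  relab <- c(A = "vMGE", B = "CGE", C = "dMGE")
  expect_equal(mcc_multiclass(relab[y], relab[p]), mcc_multiclass(y, p))
})

test_that("cross-validation honors fold structure and determinism", {
  ds <- small_dataset()
  x <- ds$matrix[, 1:10]
  lr <- make_learner("stub")
  expect_error(cross_validate(x, ds$labels, lr, folds = 50),
               "fewer samples")
  ev <- cross_validate(x, ds$labels, lr, folds = 5, seed = 2)
  # stub predicts the modal label; with equal class sizes the modal
  # training label within each fold split is data-dependent but every
  # prediction is a single class -> exactly one class has recall 1
  ia <- ev$individual_accuracy
  expect_identical(sort(unname(ia)), c(0, 0, 1))
  expect_identical(ev$acc, accuracy(ev$confusion))
  expect_equal(unname(ia), unname(individual_accuracy(ev$confusion)))
  ev2 <- cross_validate(x, ds$labels, lr, folds = 5, seed = 2)
  expect_identical(ev$confusion, ev2$confusion)
})

test_that("an oracle learner memorizing a single feature scores ACC 1", {
  sep <- separable_dataset()
  oracle_learner <- list(
    fit = function(x, y) NULL,
    predict = function(model, x) ifelse(x[, "marker"] <= 5, "A", "B"))
  ev <- cross_validate(sep$x, sep$y, oracle_learner, folds = 4,
                       stratified = TRUE, seed = 1)
  expect_identical(ev$acc, 1.0)
  expect_identical(ev$mcc, 1.0)
})

test_that("leave-one-out CV equals a brute-force per-sample loop", {
  withr::with_seed(11, {
    x <- matrix(rnorm(20 * 3), 20, 3,
                dimnames = list(NULL, paste0("g", 1:3)))
    y <- sample(c("A", "B"), 20, replace = TRUE)
  })
  y[1:2] <- c("A", "B")
  lr <- make_learner("stub")
  loo <- cross_validate(x, y, lr, folds = 20, stratified = FALSE,
                        seed = 4)
  manual <- vapply(seq_len(20), function(i) {
    tab <- table(y[-i])
    names(tab)[which.max(tab)]
  }, character(1))
  expect_identical(loo$acc, mean(manual == y))
  expect_equal(loo$confusion, confusion_matrix(y, manual))
})

test_that("repeated CV is deterministic and collapses to cross_validate", {
  ds <- small_dataset()
  x <- ds$matrix[, 1:10]
  lr <- make_learner("stub")
  once <- repeated_cv(x, ds$labels, lr, folds = 4, times = 1,
                      base_seed = 9)
  direct <- cross_validate(x, ds$labels, lr, folds = 4, seed = 9)
  expect_identical(once$results$acc, direct$acc)
  expect_identical(once$results$mcc, direct$mcc)
  twice <- repeated_cv(x, ds$labels, lr, folds = 4, times = 3,
                       base_seed = 9)
  again <- repeated_cv(x, ds$labels, lr, folds = 4, times = 3,
                       base_seed = 9)
  expect_identical(twice$results, again$results)
  expect_identical(twice$summary$mcc[["min"]], min(twice$results$mcc))
})
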