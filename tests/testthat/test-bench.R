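with_seed <- get("with_seed", asNamespace("octaco"))

balanced_table <- function(n_per_class, n_classes = 5, d = 6, sep = 3,
                           seed = 1) {
  with_seed(seed, {
    y <- rep(seq_len(n_classes), each = n_per_class)
    m <- matrix(rnorm(n_classes * d, sd = sep), n_classes, d)
    X <- m[y, ] + matrix(rnorm(length(y) * d), length(y), d)
    feature_table(X, y)
  })
}

test_that("the registry holds exactly the seven presets, with aliases", {
  expect_equal(make_preset("cubic_svm")$hyper$degree, 3)
  expect_equal(make_preset("quadratic_svm")$hyper$degree, 2)
  expect_equal(make_preset("linear_svm")$hyper$degree, 1)
  expect_equal(make_preset("Subspace decrement")$name, "subspace_discriminant")
  expect_equal(make_preset("cosine KNN")$name, "cosine_knn")
  expect_error(make_preset("rbf_svm"), "registry")
  reg <- octaco:::.preset_names
  expect_length(reg, 7)
})

test_that("a separable fixture is classified perfectly by the cubic SVM", {
  tab <- balanced_table(12, n_classes = 3, d = 2, sep = 12, seed = 2)
  ev <- crossval_evaluate(tab, presets = "cubic_svm", folds = 4, seed = 3)
  expect_equal(ev$results$accuracy, 100)
  expect_equal(sum(ev$confusion$cubic_svm), 36)
})

test_that("all presets run and conserve confusion-matrix totals", {
  tab <- balanced_table(15, n_classes = 3, d = 5, sep = 2, seed = 4)
  ev <- crossval_evaluate(tab, presets = "all", folds = 3, seed = 5)
  expect_equal(nrow(ev$results), 7)
  for (cm in ev$confusion) {
    expect_equal(sum(cm), 45)
    expect_equal(unname(rowSums(cm)), rep(15, 3))  # row sums = class counts
  }
  expect_true(all(ev$results$accuracy >= 0 & ev$results$accuracy <= 100))
  expect_true(all(ev$results$auc >= 0 & ev$results$auc <= 1))
  expect_true(all(ev$results$time >= 0))
})

test_that("every preset is scored on the identical seeded partition", {
  tab <- balanced_table(12, n_classes = 3, d = 4, seed = 6)
  ev1 <- crossval_evaluate(tab, presets = c("cosine_knn", "weighted_knn"),
                           folds = 3, seed = 7)
  ev2 <- crossval_evaluate(tab, presets = "cubic_svm", folds = 3, seed = 7)
  expect_identical(ev1$fold, ev2$fold)
  expect_identical(ev1$partition_hash, ev2$partition_hash)
  # too-small classes are rejected with guidance
  tiny <- balanced_table(3, n_classes = 2, d = 3, seed = 8)
  expect_error(crossval_evaluate(tiny, presets = "cosine_knn", folds = 5),
               "fewer folds")
})

test_that("pooled macro metrics agree with per-fold averaging on balanced data", {
  tab <- balanced_table(20, n_classes = 3, d = 5, sep = 2, seed = 9)
  ev <- crossval_evaluate(tab, presets = "weighted_knn", folds = 4, seed = 10)
  pred <- ev$predictions$weighted_knn
  y <- factor(tab$class_names[tab$labels], levels = tab$class_names)
  per_fold <- sapply(seq_len(4), function(f) {
    idx <- ev$fold == f
    cm <- table(y[idx], pred[idx])
    mean(diag(cm) / pmax(rowSums(cm), 1))
  })
  expect_lt(abs(100 * mean(per_fold) - ev$results$recall), 1)
})

test_that("random scores on a balanced binary fixture give AUC one half", {
  y <- factor(rep(c("a", "b"), each = 150))
  aucs <- vapply(1:5, function(s) with_seed(s, {
    scores <- matrix(runif(300 * 2), 300, 2, dimnames = list(NULL, c("a", "b")))
    octaco:::.macro_auc(y, scores)
  }), 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("holdout mode trains on the complement and scores the mask", {
  tab <- balanced_table(10, n_classes = 2, d = 3, sep = 6, seed = 12)
  mask <- rep(c(TRUE, FALSE), 10)
  ev <- crossval_evaluate(tab, presets = "cosine_knn", mode = "holdout",
                          holdout = mask, seed = 13)
  expect_equal(ev$n, sum(mask))
  expect_equal(sum(ev$confusion$cosine_knn), sum(mask))
  expect_error(crossval_evaluate(tab, presets = "cosine_knn",
                                 mode = "holdout"), "mask")
})

test_that("reports are written idempotently in the reference layout", {
  tab <- balanced_table(12, n_classes = 3, d = 4, sep = 4, seed = 14)
  ev <- crossval_evaluate(tab, presets = c("cubic_svm", "cosine_knn"),
                          folds = 3, seed = 15)
  dir <- tempfile("report")
  write_report(ev, dir)
  hdr <- readLines(file.path(dir, "report.csv"), n = 1)
  expect_equal(hdr, "Classifier,Accuracy,Time,AUC,Precision Rate,Recall Rate")
  expect_equal(length(readLines(file.path(dir, "report.csv"))), 3)
  expect_true(file.exists(file.path(dir, "confusion_cubic_svm.csv")))
  first <- readBin(file.path(dir, "report.csv"), "raw", 1e5)
  write_report(ev, dir)
  expect_identical(readBin(file.path(dir, "report.csv"), "raw", 1e5), first)

  ev0 <- crossval_evaluate(tab, presets = character(), folds = 3, seed = 15)
  dir0 <- tempfile("report0")
  write_report(ev0, dir0)
  expect_equal(length(readLines(file.path(dir0, "report.csv"))), 1)
})
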