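#' Classifier presets of the evaluation harness
#'
#' The registry holds exactly seven presets, named after the classifier
#' menu the reference tables report (the "subspace decrement" spelling is
#' accepted as an alias of the subspace discriminant). Hyperparameters are
#' frozen:
#' \itemize{
#'   \item `linear_svm`, `quadratic_svm`, `cubic_svm`: polynomial-kernel
#'     SVM of degree 1/2/3, box constraint 1, `coef0 = 1`, one-vs-one.
#'   \item `cosine_knn`: k = 10 nearest neighbors under cosine distance.
#'   \item `weighted_knn`: k = 10, Euclidean, squared-inverse distance
#'     vote weights.
#'   \item `subspace_knn`: random-subspace ensemble of 30 1-NN learners,
#'     subspace dimension `ceiling(d / 2)`.
#'   \item `subspace_discriminant`: random-subspace ensemble of 30 linear
#'     discriminant learners, subspace dimension `ceiling(d / 2)`.
#' }
#'
#' @param name a registry name or alias (case and space insensitive).
#' @return a `classifier_preset`.
#' @export
make_preset <- function(name) {
  key <- gsub("[ -]+", "_", tolower(trimws(name)))
  aliases <- c(subspace_decrement = "subspace_discriminant",
               csvm = "cubic_svm", qsvm = "quadratic_svm")
  if (key %in% names(aliases)) key <- aliases[[key]]
  if (!key %in% .preset_names)
    stop("unknown classifier preset '", name, "'; registry: ",
         paste(.preset_names, collapse = ", "), call. = FALSE)
  structure(list(name = key, hyper = .preset_hyper[[key]]),
            class = "classifier_preset")
}

.preset_names <- c("linear_svm", "quadratic_svm", "cubic_svm", "cosine_knn",
                   "weighted_knn", "subspace_knn", "subspace_discriminant")

.preset_hyper <- list(
  linear_svm = list(kind = "svm", degree = 1L, cost = 1, coef0 = 1),
  quadratic_svm = list(kind = "svm", degree = 2L, cost = 1, coef0 = 1),
  cubic_svm = list(kind = "svm", degree = 3L, cost = 1, coef0 = 1),
  cosine_knn = list(kind = "knn", k = 10L, metric = "cosine",
                    weights = "uniform"),
  weighted_knn = list(kind = "knn", k = 10L, metric = "euclidean",
                      weights = "squared_inverse"),
  subspace_knn = list(kind = "subspace", base = "knn1", n_learners = 30L),
  subspace_discriminant = list(kind = "subspace", base = "lda",
                               n_learners = 30L))

# ---- base learners ---------------------------------------------------------
# Each .fit_* returns a closure scoring a test matrix into a list
# (scores: n x C matrix of class scores, columns in level order).

.fit_svm <- function(X, y, hp) {
  fit <- e1071::svm(X, y, kernel = "polynomial", degree = hp$degree,
                    cost = hp$cost, coef0 = hp$coef0, gamma = 1 / ncol(X),
                    scale = FALSE, probability = TRUE)
  function(Xte) {
    pr <- predict(fit, Xte, probability = TRUE)
    p <- attr(pr, "probabilities")[, levels(y), drop = FALSE]
    # class from the decision rule itself: Platt-scaled probabilities can
    # disagree with the one-vs-one vote near the margin
    list(scores = p, class = factor(as.character(pr), levels = levels(y)))
  }
}

.knn_scores <- function(Xtr, ytr, Xte, k, metric, weights) {
  k <- min(k, nrow(Xtr))
  lv <- levels(ytr)
  if (metric == "cosine") {
    nz <- function(M) M / pmax(sqrt(rowSums(M^2)), .Machine$double.eps)
    D <- 1 - tcrossprod(nz(Xte), nz(Xtr))
  } else {
    D <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xte, Xtr)
    D[D < 0] <- 0
  }
  S <- matrix(0, nrow(Xte), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(Xte))) {
    nb <- order(D[i, ])[seq_len(k)]
    w <- if (weights == "squared_inverse")
      1 / pmax(D[i, nb], 1e-12) else rep(1, k)
    tw <- rowsum(w, ytr[nb])
    S[i, rownames(tw)] <- tw[, 1]
  }
  S / pmax(rowSums(S), .Machine$double.eps)
}

.fit_knn <- function(X, y, hp) {
  force(X); force(y)
  function(Xte) list(scores = .knn_scores(X, y, Xte, hp$k, hp$metric,
                                          hp$weights))
}

.fit_subspace <- function(X, y, hp) {
  d <- ncol(X)
  m <- ceiling(d / 2)
  lv <- levels(y)
  subspaces <- lapply(seq_len(hp$n_learners), function(i) sort(sample.int(d, m)))
  learners <- lapply(subspaces, function(js) {
    Xs <- X[, js, drop = FALSE]
    if (hp$base == "knn1") {
      list(js = js, kind = "knn1", X = Xs, y = y)
    } else {
      keep <- which(apply(Xs, 2, function(col)
        all(tapply(col, y, function(v) var(v) > 1e-10))))
      if (length(keep) < 1) return(NULL)
      fit <- tryCatch(MASS::lda(Xs[, keep, drop = FALSE], grouping = y),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      list(js = js[keep], kind = "lda", fit = fit)
    }
  })
  learners <- Filter(Negate(is.null), learners)
  if (!length(learners))
    stop("no subspace learner could be fit (degenerate features)", call. = FALSE)
  function(Xte) {
    S <- matrix(0, nrow(Xte), length(lv), dimnames = list(NULL, lv))
    for (ln in learners) {
      S <- S + if (ln$kind == "knn1") {
        .knn_scores(ln$X, ln$y, Xte[, ln$js, drop = FALSE], 1L,
                    "euclidean", "uniform")
      } else {
        predict(ln$fit, Xte[, ln$js, drop = FALSE])$posterior[, lv, drop = FALSE]
      }
    }
    list(scores = S / length(learners))
  }
}

.fit_preset <- function(preset, X, y) {
  switch(preset$hyper$kind,
         svm = .fit_svm(X, y, preset$hyper),
         knn = .fit_knn(X, y, preset$hyper),
         subspace = .fit_subspace(X, y, preset$hyper))
}

# ---- cross-validation harness ---------------------------------------------

# seeded stratified fold assignment; every class must have >= folds samples
.make_folds <- function(labels, folds, seed) {
  counts <- table(labels)
  if (any(counts < folds))
    stop("class(es) ", paste(names(counts)[counts < folds], collapse = ", "),
         " have fewer than ", folds, " samples; use fewer folds",
         call. = FALSE)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (c in unique(labels)) {
      idx <- sample(which(labels == c))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

.macro_metrics <- function(cm) {
  tp <- diag(cm)
  prec <- tp / pmax(colSums(cm), 1)   # over predicted counts
  rec <- tp / pmax(rowSums(cm), 1)    # over true counts
  list(precision = 100 * mean(prec), recall = 100 * mean(rec))
}

.macro_auc <- function(y, scores) {
  lv <- levels(y)
  aucs <- vapply(lv, function(c) {
    resp <- y == c
    if (!any(resp) || all(resp)) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, scores[, c], quiet = TRUE,
                                   levels = c(FALSE, TRUE), direction = "<")))
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Cross-validated benchmark of the classifier presets
#'
#' Evaluates each preset on one shared seeded stratified partition (the
#' fold assignment is identical across presets) with per-fold
#' standardization using training-fold statistics only. Metrics are
#' computed from pooled out-of-fold predictions: accuracy, macro precision
#' and recall (percent, from the pooled confusion matrix), macro
#' one-vs-rest AUC, and elapsed wall time per preset. `mode = "holdout"`
#' instead trains once on the non-holdout rows and scores the holdout rows
#' (the 80:20 protocol), using `holdout` as the test mask.
#'
#' @param table a [feature_table()].
#' @param presets `"all"` (default) or a character vector of registry
#'   names/aliases.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the partition and the subspace draws.
#' @param mode `"cv10"` (default) or `"holdout"`.
#' @param holdout logical mask of test rows (required for holdout mode).
#' @return an object of class `oct_eval`: a result table (`$results`),
#'   per-preset confusion matrices (`$confusion`), the fold vector, mode,
#'   seed and partition hash.
#' @export
crossval_evaluate <- function(table, presets = "all", folds = 10L, seed = 1L,
                              mode = c("cv10", "holdout"), holdout = NULL) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  if (identical(presets, "all")) presets <- .preset_names
  presets <- lapply(presets, make_preset)
  y <- factor(table$class_names[table$labels], levels = table$class_names)
  X <- table$matrix
  if (mode == "cv10") {
    stopifnot(folds >= 2)
    fold <- .make_folds(table$labels, folds, seed)
  } else {
    if (is.null(holdout) || !is.logical(holdout) || length(holdout) != nrow(X))
      stop("holdout mode needs a logical test mask of length nrow", call. = FALSE)
    fold <- ifelse(holdout, 1L, 0L)   # single scored fold
    folds <- 1L
  }
  scored <- fold >= 1L
  rows <- list()
  confusion <- list()
  predictions <- list()
  for (pi in seq_along(presets)) {
    preset <- presets[[pi]]
    t0 <- proc.time()[["elapsed"]]
    scores <- matrix(NA_real_, nrow(X), nlevels(y),
                     dimnames = list(NULL, levels(y)))
    pred_all <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
    for (f in seq_len(folds)) {
      tr <- if (mode == "cv10") fold != f else fold == 0L
      te <- if (mode == "cv10") fold == f else fold == 1L
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      std <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
      scorer <- with_seed(derive_seed(seed, "evaluate") + 131L * pi + f,
                          .fit_preset(preset, std(X[tr, , drop = FALSE]), y[tr]))
      res <- with_seed(derive_seed(seed, "evaluate") + 977L * pi + f,
                       scorer(std(X[te, , drop = FALSE])))
      scores[te, ] <- res$scores
      pred_all[te] <- res$class %||%
        factor(levels(y)[max.col(res$scores, ties.method = "first")],
               levels = levels(y))
    }
    pred <- pred_all[scored]
    truth <- y[scored]
    cm <- table(truth = truth, predicted = pred)
    mm <- .macro_metrics(cm)
    rows[[preset$name]] <- data.frame(
      classifier = preset$name,
      accuracy = 100 * mean(pred == truth),
      time = proc.time()[["elapsed"]] - t0,
      auc = .macro_auc(truth, scores[scored, , drop = FALSE]),
      precision = mm$precision,
      recall = mm$recall,
      stringsAsFactors = FALSE)
    confusion[[preset$name]] <- unclass(cm)
    predictions[[preset$name]] <- pred_all
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(classifier = character(), accuracy = numeric(),
               time = numeric(), auc = numeric(), precision = numeric(),
               recall = numeric(), stringsAsFactors = FALSE)
  rownames(results) <- NULL
  structure(list(results = results, confusion = confusion,
                 predictions = predictions,
                 cv_folds = if (mode == "cv10") as.integer(folds) else NA_integer_,
                 mode = mode, seed = as.integer(seed), fold = fold,
                 partition_hash = obj_hash(fold),
                 n = sum(scored)),
            class = "oct_eval")
}

#' @export
print.oct_eval <- function(x, ...) {
  cat(sprintf("Classifier benchmark (%s%s, n = %d):\n", x$mode,
              if (x$mode == "cv10") paste0(", ", x$cv_folds, " folds") else "",
              x$n))
  df <- x$results
  df$accuracy <- sprintf("%.1f%%", df$accuracy)
  df$time <- sprintf("%.1f s", df$time)
  df$auc <- sprintf("%.2f", df$auc)
  df$precision <- sprintf("%.1f", df$precision)
  df$recall <- sprintf("%.1f", df$recall)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' One delimited table (`report.csv`) with columns Classifier, Accuracy,
#' Time, AUC, Precision Rate, Recall Rate, plus one confusion-matrix CSV
#' per classifier. Re-writing the same report is byte-identical.
#'
#' @param report an `oct_eval`.
#' @param dir output directory (created if needed).
#' @return the report path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "oct_eval"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- report$results
  out <- data.frame(Classifier = df$classifier,
                    Accuracy = df$accuracy,
                    Time = df$time,
                    AUC = df$auc,
                    `Precision Rate` = df$precision,
                    `Recall Rate` = df$recall,
                    check.names = FALSE)
  path <- file.path(dir, "report.csv")
  data.table::fwrite(out, path)
  for (nm in names(report$confusion)) {
    cm <- as.data.frame.matrix(report$confusion[[nm]])
    cm <- cbind(truth = rownames(cm), cm)
    data.table::fwrite(cm, file.path(dir, paste0("confusion_", nm, ".csv")))
  }
  invisible(path)
}
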