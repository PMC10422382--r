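#' Training configuration for head fine-tuning
#'
#' Defaults follow the experimental protocol: SGD, 100 epochs, minibatch
#' 64, learning rate 1e-4 (a 1e-5 variant is reported for DenseNet-201
#' training and can be set here).
#'
#' @param epochs number of passes over the training split.
#' @param learning_rate SGD step size.
#' @param minibatch minibatch size.
#' @param seed integer seed governing minibatch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         minibatch = 64L, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate >= 0, minibatch >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 minibatch = as.integer(minibatch), seed = as.integer(seed),
                 optimizer = "sgd"),
            class = "train_config")
}

# forward the body over manifest records, returning the pooled feature
# matrix in record order
.pooled_features <- function(model, records) {
  t(vapply(records$path, function(p) {
    img <- preprocess_image(read_oct_image(p), model$spec$input_size[1])
    forward_graph(model$nodes, img, model$gap_node)
  }, numeric(model$feature_dim), USE.NAMES = FALSE))
}

#' Fine-tune the classification head of a modified backbone
#'
#' Transfer learning in the linear-probe regime: the convolutional body is
#' kept frozen, its global-average-pool activations are computed once for
#' the training split, and the new `num_classes` head is trained by
#' minibatch SGD on the softmax cross-entropy loss. Pooled features are
#' standardized (mean/sd of the training split) before the head; the
#' scaling is stored in the model so logits are well-defined at
#' prediction time.
#'
#' @param model an `oct_backbone` from [build_modified_backbone()].
#' @param m an `image_manifest` with a train split assigned.
#' @param cfg a [train_config()].
#' @return list with elements `model` (head-updated backbone, `trained =
#'   TRUE`), `loss_history` (one mean cross-entropy value per epoch) and
#'   `train_accuracy`.
#' @export
finetune <- function(model, m, cfg = train_config()) {
  stopifnot(inherits(model, "oct_backbone"), inherits(m, "image_manifest"),
            inherits(cfg, "train_config"))
  rec <- m$records[m$records$split == "train", , drop = FALSE]
  if (!nrow(rec)) stop("manifest has an empty train split", call. = FALSE)
  y <- match(rec$class_name, m$class_names)
  C <- model$spec$num_classes
  stopifnot(length(m$class_names) == C)
  X <- .pooled_features(model, rec)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  W <- model$head$W
  bb <- model$head$b
  n <- nrow(Xs)
  Y <- diag(C)[y, , drop = FALSE]
  losses <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = cfg$minibatch)) {
        idx <- ord[start:min(start + cfg$minibatch - 1, n)]
        Xb <- Xs[idx, , drop = FALSE]
        logits <- sweep(Xb %*% t(W), 2, bb, "+")
        logits <- logits - apply(logits, 1, max)
        P <- exp(logits)
        P <- P / rowSums(P)
        batch_losses <- c(batch_losses,
                          -mean(log(pmax(P[cbind(seq_along(idx), y[idx])], 1e-12))))
        G <- (P - Y[idx, , drop = FALSE]) / length(idx)
        W <- W - cfg$learning_rate * t(G) %*% Xb
        bb <- bb - cfg$learning_rate * colSums(G)
      }
      losses[ep] <- mean(batch_losses)
    }
  })
  model$head$W <- W
  model$head$b <- bb
  model$head$scale <- list(mean = mu, sd = sdv)
  model$trained <- TRUE
  logits <- sweep(Xs %*% t(W), 2, bb, "+")
  acc <- mean(max.col(logits, ties.method = "first") == y)
  list(model = model, loss_history = losses, train_accuracy = acc)
}

#' Predict class labels for manifest images
#'
#' @param object an `oct_backbone` (typically after [finetune()]).
#' @param m an `image_manifest`; all records are scored.
#' @param ... unused.
#' @return factor of predicted class names, in record order.
#' @export
predict.oct_backbone <- function(object, m, ...) {
  stopifnot(inherits(m, "image_manifest"))
  X <- .pooled_features(object, m$records)
  if (!is.null(object$head$scale)) {
    X <- sweep(sweep(X, 2, object$head$scale$mean, "-"), 2,
               object$head$scale$sd, "/")
  }
  logits <- sweep(X %*% t(object$head$W), 2, object$head$b, "+")
  factor(m$class_names[max.col(logits, ties.method = "first")],
         levels = m$class_names)
}

#' Export deep features from the global-average-pool layer
#'
#' Runs every selected manifest record through the backbone body and
#' collects the pooled activations (raw, unstandardized) into a
#' [feature_table()]. Row order matches manifest record order. Works with
#' untrained (randomly initialized) backbones: the shape and ordering
#' contracts do not depend on training.
#'
#' @param model an `oct_backbone`.
#' @param m an `image_manifest`.
#' @param split which records to export: `"all"` (default), `"train"` or
#'   `"test"`.
#' @return a `feature_table` with provenance (backbone name, feature layer,
#'   head fingerprint, training state).
#' @export
extract_features <- function(model, m, split = c("all", "train", "test")) {
  stopifnot(inherits(model, "oct_backbone"), inherits(m, "image_manifest"))
  split <- match.arg(split)
  rec <- m$records
  if (split != "all") rec <- rec[rec$split == split, , drop = FALSE]
  if (!nrow(rec)) stop("no manifest records in split '", split, "'", call. = FALSE)
  X <- .pooled_features(model, rec)
  feature_table(
    X, match(rec$class_name, m$class_names), m$class_names,
    provenance = list(backbone = model$spec$name,
                      feature_layer = model$spec$feature_layer,
                      trained = model$trained,
                      fingerprint = obj_hash(model$head),
                      split = split))
}
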