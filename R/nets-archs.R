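# Architecture definitions for the three modified backbones. Each builder
# returns the node graph of the convolutional body ending in a
# global-average-pool node; the 5-class head is attached separately so head
# surgery never touches body weights.

.supported_backbones <- c("resnet50", "densenet201", "inceptionv3")

build_resnet50_body <- function() {
  b <- nb_new()
  x <- nb_input(b, 3L)
  x <- nb_conv_bn_relu(b, x, 7, 64, stride = 2, pad = 3)
  x <- nb_pool(b, x, "maxpool", 3, stride = 2, pad = 1)
  bottleneck <- function(x, mid, out, stride) {
    ident <- x
    y <- nb_conv_bn_relu(b, x, 1, mid, stride = 1, pad = "valid")
    y <- nb_conv_bn_relu(b, y, 3, mid, stride = stride, pad = 1)
    y <- nb_bn(b, nb_conv(b, y, 1, out, stride = 1, pad = "valid"))
    if (stride != 1 || nb_out_ch(b, ident) != out)
      ident <- nb_bn(b, nb_conv(b, ident, 1, out, stride = stride, pad = "valid"))
    nb_relu(b, nb_add_op(b, y, ident))
  }
  stages <- list(c(3, 64, 256, 1), c(4, 128, 512, 2),
                 c(6, 256, 1024, 2), c(3, 512, 2048, 2))
  for (st in stages) {
    n_blocks <- st[1]; mid <- st[2]; out <- st[3]; s1 <- st[4]
    for (k in seq_len(n_blocks))
      x <- bottleneck(x, mid, out, if (k == 1) s1 else 1)
  }
  g <- nb_gap(b, x)
  list(nodes = b$nodes, gap_node = g, feature_dim = nb_out_ch(b, g))
}

build_densenet201_body <- function(growth = 32L) {
  b <- nb_new()
  x <- nb_input(b, 3L)
  x <- nb_conv_bn_relu(b, x, 7, 64, stride = 2, pad = 3)
  x <- nb_pool(b, x, "maxpool", 3, stride = 2, pad = 1)
  dense_layer <- function(x) {
    y <- nb_bn_relu(b, x)
    y <- nb_conv(b, y, 1, 4L * growth, pad = "valid")
    y <- nb_bn_relu(b, y)
    y <- nb_conv(b, y, 3, growth, pad = 1)
    nb_concat(b, c(x, y))
  }
  blocks <- c(6L, 12L, 48L, 32L)
  for (bi in seq_along(blocks)) {
    for (k in seq_len(blocks[bi])) x <- dense_layer(x)
    if (bi < length(blocks)) {  # transition: halve channels, downsample
      y <- nb_bn_relu(b, x)
      y <- nb_conv(b, y, 1, nb_out_ch(b, x) %/% 2L, pad = "valid")
      x <- nb_pool(b, y, "avgpool", 2, stride = 2)
    }
  }
  x <- nb_bn_relu(b, x)
  g <- nb_gap(b, x)
  list(nodes = b$nodes, gap_node = g, feature_dim = nb_out_ch(b, g))
}

build_inceptionv3_body <- function() {
  b <- nb_new()
  x <- nb_input(b, 3L)
  x <- nb_conv_bn_relu(b, x, 3, 32, stride = 2, pad = "valid")
  x <- nb_conv_bn_relu(b, x, 3, 32, pad = "valid")
  x <- nb_conv_bn_relu(b, x, 3, 64, pad = 1)
  x <- nb_pool(b, x, "maxpool", 3, stride = 2)
  x <- nb_conv_bn_relu(b, x, 1, 80, pad = "valid")
  x <- nb_conv_bn_relu(b, x, 3, 192, pad = "valid")
  x <- nb_pool(b, x, "maxpool", 3, stride = 2)
  cbr <- function(x, k, out, stride = 1, pad = "same")
    nb_conv_bn_relu(b, x, k, out, stride = stride, pad = pad)
  inception_a <- function(x, pool_ch) {
    b1 <- cbr(x, 1, 64)
    b5 <- cbr(cbr(x, 1, 48), 5, 64, pad = 2)
    b3 <- cbr(cbr(cbr(x, 1, 64), 3, 96, pad = 1), 3, 96, pad = 1)
    bp <- cbr(nb_pool(b, x, "avgpool", 3, stride = 1, pad = 1), 1, pool_ch)
    nb_concat(b, c(b1, b5, b3, bp))
  }
  reduction_a <- function(x) {
    b3 <- cbr(x, 3, 384, stride = 2, pad = "valid")
    bd <- cbr(cbr(cbr(x, 1, 64), 3, 96, pad = 1), 3, 96, stride = 2, pad = "valid")
    bp <- nb_pool(b, x, "maxpool", 3, stride = 2)
    nb_concat(b, c(b3, bd, bp))
  }
  inception_b <- function(x, c7) {
    b1 <- cbr(x, 1, 192)
    b7 <- cbr(cbr(cbr(x, 1, c7), c(1, 7), c7), c(7, 1), 192)
    bd <- cbr(cbr(cbr(cbr(cbr(x, 1, c7), c(7, 1), c7), c(1, 7), c7),
                  c(7, 1), c7), c(1, 7), 192)
    bp <- cbr(nb_pool(b, x, "avgpool", 3, stride = 1, pad = 1), 1, 192)
    nb_concat(b, c(b1, b7, bd, bp))
  }
  reduction_b <- function(x) {
    b3 <- cbr(cbr(x, 1, 192), 3, 320, stride = 2, pad = "valid")
    b7 <- cbr(cbr(cbr(cbr(x, 1, 192), c(1, 7), 192), c(7, 1), 192),
              3, 192, stride = 2, pad = "valid")
    bp <- nb_pool(b, x, "maxpool", 3, stride = 2)
    nb_concat(b, c(b3, b7, bp))
  }
  inception_c <- function(x) {
    b1 <- cbr(x, 1, 320)
    s <- cbr(x, 1, 384)
    b3 <- nb_concat(b, c(cbr(s, c(1, 3), 384), cbr(s, c(3, 1), 384)))
    sd <- cbr(cbr(x, 1, 448), 3, 384, pad = 1)
    bd <- nb_concat(b, c(cbr(sd, c(1, 3), 384), cbr(sd, c(3, 1), 384)))
    bp <- cbr(nb_pool(b, x, "avgpool", 3, stride = 1, pad = 1), 1, 192)
    nb_concat(b, c(b1, b3, bd, bp))
  }
  for (pc in c(32, 64, 64)) x <- inception_a(x, pc)
  x <- reduction_a(x)
  for (c7 in c(128, 160, 160, 192)) x <- inception_b(x, c7)
  x <- reduction_b(x)
  for (k in 1:2) x <- inception_c(x)
  g <- nb_gap(b, x)
  list(nodes = b$nodes, gap_node = g, feature_dim = nb_out_ch(b, g))
}

#' Build a modified backbone with a replaced classification head
#'
#' Instantiates one of the three supported convolutional architectures
#' (ResNet-50, DenseNet-201, InceptionV3) at a fixed 224 x 224 x 3 input,
#' drops the original 1000-class fully connected layer, and attaches a new
#' head with `num_classes` output units fed by the global-average-pool
#' activation. The pooled widths are the architectural ones: 2048 for
#' ResNet-50, 1920 for DenseNet-201, 2048 for InceptionV3.
#'
#' ImageNet-pretrained weights are not bundled; the default is a seeded
#' He-normal initialization, which satisfies every shape and ordering
#' contract of the downstream pipeline. To use pretrained weights, pass
#' `weights_file` (an RDS list of node weight arrays as produced by
#' [backbone_weights()]).
#'
#' @param name one of `"resnet50"`, `"densenet201"`, `"inceptionv3"`.
#' @param num_classes number of output classes for the new head (default 5,
#'   the five retinal disease classes).
#' @param pretrained logical; if TRUE, `weights_file` must be supplied.
#' @param weights_file optional RDS file with body weights to load.
#' @param seed integer seed for weight initialization.
#' @param input_size input geometry; fixed at `c(224, 224, 3)`.
#' @return an object of class `oct_backbone`.
#' @export
build_modified_backbone <- function(name, num_classes = 5L, pretrained = FALSE,
                                    weights_file = NULL, seed = 1L,
                                    input_size = c(224L, 224L, 3L)) {
  if (!name %in% .supported_backbones)
    stop("unsupported backbone '", name, "'; supported: ",
         paste(.supported_backbones, collapse = ", "), call. = FALSE)
  stopifnot(num_classes >= 2, identical(as.integer(input_size),
                                        c(224L, 224L, 3L)))
  if (pretrained && is.null(weights_file))
    stop("pretrained weights are not bundled; supply weights_file or use ",
         "pretrained = FALSE (seeded random initialization)", call. = FALSE)
  body <- with_seed(as.integer(seed), switch(name,
    resnet50 = build_resnet50_body(),
    densenet201 = build_densenet201_body(),
    inceptionv3 = build_inceptionv3_body()))
  if (!is.null(weights_file)) {
    w <- readRDS(weights_file)
    stopifnot(length(w) == length(body$nodes))
    for (i in seq_along(w)) {
      if (!is.null(w[[i]]$w)) body$nodes[[i]]$w <- w[[i]]$w
      if (!is.null(w[[i]]$gamma)) {
        body$nodes[[i]]$gamma <- w[[i]]$gamma
        body$nodes[[i]]$beta <- w[[i]]$beta
      }
    }
  }
  d <- body$feature_dim
  head <- with_seed(as.integer(seed) + 1L, list(
    W = matrix(rnorm(num_classes * d, sd = sqrt(1 / d)), num_classes, d),
    b = rep(0, num_classes)))
  structure(list(
    spec = list(name = name, input_size = c(224L, 224L, 3L),
                pretrained = pretrained, num_classes = as.integer(num_classes),
                feature_layer = "global_avg_pool", seed = as.integer(seed)),
    nodes = body$nodes, gap_node = body$gap_node, feature_dim = d,
    head = head, trained = FALSE),
    class = "oct_backbone")
}

#' @export
print.oct_backbone <- function(x, ...) {
  cat(sprintf("Modified %s: %d nodes, pooled feature width %d, %d-class head%s\n",
              x$spec$name, length(x$nodes), x$feature_dim,
              x$spec$num_classes,
              if (x$trained) " (head trained)" else " (untrained)"))
  invisible(x)
}

#' Extract the body weights of a backbone
#'
#' Returns the per-node weight list (conv kernels and batch-norm affine
#' parameters; the classification head is excluded). Useful for
#' checksumming — head surgery must leave these untouched — and as the
#' on-disk weight format accepted by [build_modified_backbone()].
#'
#' @param model an `oct_backbone`.
#' @return list, one element per graph node.
#' @export
backbone_weights <- function(model) {
  stopifnot(inherits(model, "oct_backbone"))
  lapply(model$nodes, function(nd)
    nd[intersect(names(nd), c("w", "gamma", "beta"))])
}

#' Forward pass through a backbone
#'
#' @param model an `oct_backbone`.
#' @param img either a preprocessed `224 x 224 x 3` array (see
#'   [preprocess_image()]) or a list of such arrays (a batch).
#' @param output `"logits"` (default) for the head output, `"features"` for
#'   the global-average-pool activation (the inspection hook).
#' @return a matrix with one row per input image (`num_classes` columns for
#'   logits, `feature_dim` for features).
#' @export
forward_backbone <- function(model, img, output = c("logits", "features")) {
  stopifnot(inherits(model, "oct_backbone"))
  output <- match.arg(output)
  batch <- if (is.list(img)) img else list(img)
  feats <- t(vapply(batch, function(x) {
    stopifnot(identical(dim(x), c(224L, 224L, 3L)) ||
              identical(dim(x), c(224, 224, 3)))
    forward_graph(model$nodes, x, model$gap_node)
  }, numeric(model$feature_dim)))
  if (output == "features") return(feats)
  sweep(feats %*% t(model$head$W), 2, model$head$b, "+")
}
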