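# Minimal DAG builder + forward executor for convolutional backbones.
# Nodes are layer descriptors; weights are created at build time from the
# active RNG stream (He-normal fan-in initialization). Batch-norm layers are
# carried as per-channel affine transforms (inference form); at
# initialization they are the identity.

nb_new <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b
}

nb_add <- function(b, node) {
  # force the descriptor before touching b$nodes: node construction may
  # itself append nodes (lazily evaluated nested builder calls)
  force(node)
  b$nodes[[length(b$nodes) + 1L]] <- node
  length(b$nodes)
}

nb_input <- function(b, channels = 3L) {
  nb_add(b, list(op = "input", inputs = integer(), out_ch = channels))
}

nb_out_ch <- function(b, i) {
  force(i)  # i may be an unevaluated builder call that appends to b$nodes
  b$nodes[[i]]$out_ch
}

# pad spec -> c(pt, pb, pl, pr); "same" follows the floor((k-1)/2) rule
.pad4 <- function(pad, kh, kw) {
  if (identical(pad, "valid")) return(c(0L, 0L, 0L, 0L))
  if (identical(pad, "same")) {
    pt <- (kh - 1L) %/% 2L
    pl <- (kw - 1L) %/% 2L
    return(as.integer(c(pt, kh - 1L - pt, pl, kw - 1L - pl)))
  }
  pad <- as.integer(pad)
  if (length(pad) == 1) return(rep(pad, 4L))
  if (length(pad) == 2) return(c(pad[1], pad[1], pad[2], pad[2]))
  stopifnot(length(pad) == 4)
  pad
}

nb_conv <- function(b, x, k, out_ch, stride = 1L, pad = "same") {
  force(x)
  k <- as.integer(if (length(k) == 1) c(k, k) else k)
  in_ch <- nb_out_ch(b, x)
  fan_in <- k[1] * k[2] * in_ch
  w <- matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)), fan_in, out_ch)
  nb_add(b, list(op = "conv", inputs = x, out_ch = as.integer(out_ch),
                 kh = k[1], kw = k[2], stride = as.integer(stride),
                 pad = .pad4(pad, k[1], k[2]), w = w))
}

nb_bn <- function(b, x) {
  force(x)
  ch <- nb_out_ch(b, x)
  nb_add(b, list(op = "bn", inputs = x, out_ch = ch,
                 gamma = rep(1, ch), beta = rep(0, ch)))
}

nb_relu <- function(b, x) {
  force(x)
  nb_add(b, list(op = "relu", inputs = x, out_ch = nb_out_ch(b, x)))
}

nb_bn_relu <- function(b, x) nb_relu(b, nb_bn(b, x))

nb_conv_bn_relu <- function(b, x, k, out_ch, stride = 1L, pad = "same") {
  nb_bn_relu(b, nb_conv(b, x, k, out_ch, stride, pad))
}

nb_pool <- function(b, x, type, k, stride = NULL, pad = "valid") {
  force(x)
  k <- as.integer(if (length(k) == 1) c(k, k) else k)
  stride <- as.integer(stride %||% k[1])
  nb_add(b, list(op = type, inputs = x, out_ch = nb_out_ch(b, x),
                 kh = k[1], kw = k[2], stride = stride,
                 pad = .pad4(pad, k[1], k[2])))
}

nb_add_op <- function(b, x, y) {
  force(x); force(y)
  stopifnot(nb_out_ch(b, x) == nb_out_ch(b, y))
  nb_add(b, list(op = "add", inputs = c(x, y), out_ch = nb_out_ch(b, x)))
}

nb_concat <- function(b, xs) {
  xs <- as.integer(xs)
  nb_add(b, list(op = "concat", inputs = as.integer(xs),
                 out_ch = sum(vapply(xs, function(i) nb_out_ch(b, i), 0L))))
}

nb_gap <- function(b, x) {
  force(x)
  nb_add(b, list(op = "gap", inputs = x, out_ch = nb_out_ch(b, x)))
}

# Forward pass of the node graph on one H x W x C input array.
# Returns the value of node `out` (for a gap node: the pooled feature vector).
forward_graph <- function(nodes, x, out = length(nodes)) {
  n <- length(nodes)
  last_use <- integer(n)
  for (j in seq_len(n)) for (i in nodes[[j]]$inputs) last_use[i] <- j
  last_use[out] <- n + 1L
  vals <- vector("list", n)
  for (j in seq_len(min(out, n))) {
    nd <- nodes[[j]]
    v <- switch(nd$op,
      input = x,
      conv = {
        inp <- vals[[nd$inputs]]
        conv2d_fwd(inp, nd$w, nd$kh, nd$kw, nd$stride,
                   nd$pad[1], nd$pad[2], nd$pad[3], nd$pad[4])
      },
      bn = {
        inp <- vals[[nd$inputs]]
        if (all(nd$gamma == 1) && all(nd$beta == 0)) inp
        else {
          d <- dim(inp)
          sweep(sweep(inp, 3, nd$gamma, "*"), 3, nd$beta, "+")
        }
      },
      relu = pmax(vals[[nd$inputs]], 0),
      maxpool = {
        inp <- vals[[nd$inputs]]
        maxpool_fwd(inp, nd$kh, nd$kw, nd$stride,
                    nd$pad[1], nd$pad[2], nd$pad[3], nd$pad[4])
      },
      avgpool = {
        inp <- vals[[nd$inputs]]
        avgpool_fwd(inp, nd$kh, nd$kw, nd$stride,
                    nd$pad[1], nd$pad[2], nd$pad[3], nd$pad[4])
      },
      add = vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]],
      concat = {
        parts <- vals[nd$inputs]
        d <- dim(parts[[1]])
        array(unlist(parts, use.names = FALSE),
              dim = c(d[1], d[2], nd$out_ch))
      },
      gap = {
        inp <- vals[[nd$inputs]]
        colMeans(matrix(inp, ncol = dim(inp)[3]))
      },
      stop("unknown op: ", nd$op)
    )
    vals[[j]] <- v
    for (i in nd$inputs) if (last_use[i] == j) vals[i] <- list(NULL)
  }
  vals[[out]]
}
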