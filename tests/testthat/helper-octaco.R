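# Shared fixtures, built once per test session (backbone builds and image
# forwards are the expensive pieces).

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# 5-class stylized OCT tree, 4 images per class, small frames
oct_tree <- function() {
  cached("oct_tree", {
    d <- file.path(tempdir(), "octaco-tree")
    unlink(d, recursive = TRUE)
    make_synthetic_oct(d, class_counts = c(ARMD = 4, BRVO = 4, CRVO = 4,
                                           CSCR = 4, DME = 4),
                       image_size = c(120, 400), seed = 42)
  })
}

oct_manifest <- function() {
  cached("oct_manifest", split_manifest(oct_tree(), 0.25, seed = 11))
}

resnet <- function() {
  cached("resnet", build_modified_backbone("resnet50", seed = 1))
}

# pooled features of the full 20-image tree under the cached backbone
oct_features <- function() {
  cached("oct_features", extract_features(resnet(), oct_manifest()))
}

# a generic directory-per-class tree of tiny noise images, for IO tests
noise_tree <- function(classes, n_per_class, dir = tempfile("noise-tree")) {
  for (cl in classes) {
    d <- file.path(dir, cl)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_per_class))
      png::writePNG(matrix(runif(64), 8, 8),
                    file.path(d, sprintf("img%02d.png", i)))
  }
  dir
}

# directory-per-class tree of empty placeholder files (for split arithmetic
# at realistic class counts without the cost of rendering images)
placeholder_tree <- function(counts, dir = tempfile("placeholder-tree")) {
  for (cl in names(counts)) {
    d <- file.path(dir, cl)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    file.create(file.path(d, sprintf("%s_%04d.png", cl, seq_len(counts[[cl]]))))
  }
  dir
}

# two-class planted instance with deterministic signed class means on the
# informative features (gap in units of the unit noise sd) and pure-noise
# remainder; the clearly-separated regime where the exhaustive 1-NN optimum
# is signal-determined
planted_instance <- function(n_per_class = 20, n_informative = 3,
                             n_noise = 5, gap = 3, seed = 1) {
  with_seed <- get("with_seed", asNamespace("octaco"))
  with_seed(seed, {
    y <- rep(1:2, each = n_per_class)
    sgn <- ifelse(y == 1, -1, 1)
    Xi <- sapply(seq_len(n_informative), function(j) sgn * gap / 2 + rnorm(length(y)))
    Xn <- matrix(rnorm(length(y) * n_noise), ncol = n_noise)
    feature_table(cbind(Xi, Xn), y)
  })
}

# small labelled table: y determined by the sign of planted column 1
sign_table <- function(n = 40, d = 5, seed = 3) {
  with_seed <- get("with_seed", asNamespace("octaco"))
  with_seed(seed, {
    x1 <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
    X <- cbind(x1, matrix(rnorm(n * (d - 1)), n, d - 1))
    feature_table(X, ifelse(x1 < 0, 1L, 2L), class_names = c("neg", "pos"))
  })
}
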