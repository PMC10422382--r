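#' Synthetic planted feature table
#'
#' Generates an N x d feature table with known ground truth: each of
#' `n_informative` planted features carries class-dependent means (drawn
#' once per class/feature from a normal with standard deviation
#' `class_sep`, so `class_sep` is the between-class effect size in units of
#' the within-class noise), while `n_noise` features are iid standard
#' normal. Columns are randomly permuted; the returned `planted` indices
#' locate the informative columns, so selector recovery can be scored.
#'
#' @param n_per_class samples per class (default 100).
#' @param n_classes number of classes (default 5).
#' @param n_informative number of planted informative features (default 10).
#' @param n_noise number of pure-noise features (default 90).
#' @param class_sep between-class effect size (default 2).
#' @param noise_sd within-class standard deviation on informative features
#'   (default 1).
#' @param seed integer seed; generation is a pure function of the spec and
#'   seed.
#' @return list with `table` (a [feature_table()]), `planted` (sorted
#'   informative column indices) and `class_means` (the planted
#'   class-by-feature mean matrix, columns in planted-index order).
#' @export
make_planted_table <- function(n_per_class = 100L, n_classes = 5L,
                               n_informative = 10L, n_noise = 90L,
                               class_sep = 2, noise_sd = 1, seed = 1L) {
  stopifnot(n_informative >= 1, n_per_class >= 1, n_classes >= 2,
            n_noise >= 0)
  if (n_informative + n_noise == 0)
    stop("need at least one feature", call. = FALSE)
  n <- n_per_class * n_classes
  d <- n_informative + n_noise
  with_seed(as.integer(seed), {
    labels <- rep(seq_len(n_classes), each = n_per_class)
    m <- matrix(rnorm(n_classes * n_informative, sd = class_sep),
                n_classes, n_informative)
    Xi <- m[labels, , drop = FALSE] +
      matrix(rnorm(n * n_informative, sd = noise_sd), n, n_informative)
    Xn <- matrix(rnorm(n * n_noise), n, n_noise)
    perm <- sample.int(d)
    X <- cbind(Xi, Xn)[, order(perm), drop = FALSE]
    ord <- order(perm[seq_len(n_informative)])
    planted <- perm[seq_len(n_informative)][ord]
    m <- m[, ord, drop = FALSE]  # class_means columns follow planted order
    list(table = feature_table(X, labels,
                               class_names = paste0("class", seq_len(n_classes)),
                               provenance = list(backbone = "synthetic_planted",
                                                 feature_layer = "none",
                                                 seed = as.integer(seed))),
         planted = planted,
         class_means = m)
  })
}

# archetype parameters for the five stylized disease classes
.oct_classes <- c("ARMD", "BRVO", "CRVO", "CSCR", "DME")

# reference per-class image counts of the emulated dataset, scaled down 20x
.oct_default_counts <- function() {
  setNames(as.integer(round_half_up(c(738, 440, 313, 748, 759) / 20)),
           .oct_classes)
}

# render one stylized B-scan: bright horizontal retinal band over a dim
# speckled background, plus a class-specific perturbation
.render_oct <- function(h, w, class_name) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  band_c <- h * runif(1, 0.42, 0.58)
  band_hw <- h * runif(1, 0.06, 0.09)
  img <- 0.08 + 0.04 * matrix(runif(h * w), h, w)            # speckle floor
  band <- 0.65 * exp(-((rows - band_c) / band_hw)^2)
  surface <- 0.25 * exp(-((rows - band_c + 2.2 * band_hw) / (0.35 * band_hw))^2)
  img <- img + band + surface
  blob <- function(cy, cx, ry, rx, amp) {
    amp * exp(-(((rows - cy) / ry)^2 + ((cols - cx) / rx)^2))
  }
  switch(class_name,
    ARMD = {  # drusen-like bright bumps under the band
      for (k in seq_len(sample(4:7, 1)))
        img <- img + blob(band_c + band_hw * runif(1, 0.8, 1.6),
                          w * runif(1, 0.1, 0.9),
                          band_hw * runif(1, 0.5, 0.9), w * 0.015, 0.45)
      img
    },
    BRVO = {  # hemi-lateral band thickening
      side <- sample(c(-1, 1), 1)
      half <- 1 / (1 + exp(-side * (cols - w / 2) / (0.02 * w)))
      img + half * 0.5 * exp(-((rows - band_c) / (2.4 * band_hw))^2)
    },
    CRVO = {  # diffuse global thickening and brightening
      img + 0.35 * exp(-((rows - band_c) / (3.2 * band_hw))^2)
    },
    CSCR = {  # serous dome: dark fluid pocket beneath an elevated band
      img - blob(band_c + band_hw * 2.5, w * runif(1, 0.35, 0.65),
                 band_hw * 2.0, w * runif(1, 0.10, 0.16), 0.5) +
        blob(band_c - band_hw * 1.2, w / 2, band_hw * 1.2, w * 0.2, 0.18)
    },
    DME = {  # intraretinal cystic dark blobs
      for (k in seq_len(sample(3:6, 1)))
        img <- img - blob(band_c + band_hw * runif(1, -0.8, 0.8),
                          w * runif(1, 0.15, 0.85),
                          band_hw * runif(1, 0.5, 0.8),
                          w * runif(1, 0.01, 0.02), 0.55)
      img
    },
    stop("unknown synthetic class: ", class_name))
}

#' Generate a synthetic directory-per-class OCT-like image tree
#'
#' Writes seeded, stylized grayscale B-scan PNGs: a bright horizontal
#' retinal-layer band over a speckled background, with one lesion archetype
#' per class (drusen-like bumps, hemi-lateral thickening, diffuse
#' thickening, a serous dome, cystic dark blobs), so the five classes are
#' pairwise distinguishable by construction. Geometry emulates the source
#' acquisitions: unless `image_size` is fixed, each image samples its
#' height from 300-350 px and width from 1000-1050 px. These are texture
#' caricatures for exercising the pipeline, not anatomically faithful
#' renders.
#'
#' @param out_dir output directory (created if needed); one subdirectory
#'   per class.
#' @param class_counts named integer vector of images per class; the
#'   default is the reference five-class distribution scaled down 20x
#'   (37/22/16/37/38).
#' @param image_size optional fixed `c(height, width)`; default NULL
#'   samples per-image sizes from the emulated ranges.
#' @param seed integer seed; same spec + seed gives byte-identical files.
#' @return the manifest of written files, as from [scan_dataset()].
#' @export
make_synthetic_oct <- function(out_dir, class_counts = .oct_default_counts(),
                               image_size = NULL, seed = 1L) {
  stopifnot(length(class_counts) >= 2, !is.null(names(class_counts)))
  class_counts <- setNames(as.integer(class_counts), names(class_counts))
  if (any(class_counts <= 0))
    stop("all class counts must be positive", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(as.integer(seed), {
    for (cl in names(class_counts)) {
      d <- file.path(out_dir, cl)
      dir.create(d, showWarnings = FALSE)
      for (i in seq_len(class_counts[[cl]])) {
        if (is.null(image_size)) {
          h <- sample(300:350, 1)
          w <- sample(1000:1050, 1)
        } else {
          h <- image_size[1]; w <- image_size[2]
        }
        img <- .render_oct(h, w, cl)
        img[img < 0] <- 0
        img[img > 1] <- 1
        png::writePNG(img, file.path(d, sprintf("%s_%04d.png", tolower(cl), i)))
      }
    }
  })
  scan_dataset(out_dir, class_names = names(class_counts))
}
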