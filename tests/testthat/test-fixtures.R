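with_seed <- get("with_seed", asNamespace("octaco"))

test_that("planted tables are pure functions of spec and seed", {
  a <- make_planted_table(n_per_class = 10, n_classes = 3, n_informative = 3,
                          n_noise = 5, seed = 21)
  b <- make_planted_table(n_per_class = 10, n_classes = 3, n_informative = 3,
                          n_noise = 5, seed = 21)
  expect_identical(a$table$matrix, b$table$matrix)
  expect_identical(a$planted, b$planted)
  c <- make_planted_table(n_per_class = 10, n_classes = 3, n_informative = 3,
                          n_noise = 5, seed = 22)
  expect_false(identical(a$table$matrix, c$table$matrix))
  expect_length(a$planted, 3)
  expect_equal(dim(a$table$matrix), c(30, 8))
})

test_that("class-conditional means match the planted means within 3 SE", {
  n <- 200
  pt <- make_planted_table(n_per_class = n, n_classes = 3, n_informative = 4,
                           n_noise = 2, class_sep = 2, noise_sd = 1, seed = 23)
  X <- pt$table$matrix[, pt$planted, drop = FALSE]
  y <- pt$table$labels
  se <- 1 / sqrt(n)
  for (c in 1:3) {
    emp <- colMeans(X[y == c, , drop = FALSE])
    expect_true(all(abs(emp - pt$class_means[c, ]) < 3 * se))
  }
})

test_that("planted features out-rank noise in Fisher visibility at class_sep 2", {
  # generator defaults: 5 classes x 100 samples, 10 informative + 90 noise
  hits <- vapply(1:100, function(s) {
    pt <- make_planted_table(class_sep = 2, seed = s)
    v <- fisher_visibility(pt$table)
    min(v[pt$planted]) > max(v[-pt$planted])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a null-signal table yields chance-level fitness", {
  pt <- make_planted_table(n_per_class = 100, n_classes = 2, n_informative = 1,
                           n_noise = 5, class_sep = 0, seed = 31)
  f <- subset_fitness(pt$table, 1:6, aco_config(seed = 1))
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 60))
})

test_that("synthetic OCT trees are seeded, counted, and byte-stable", {
  counts <- c(ARMD = 2, BRVO = 2, CRVO = 2, CSCR = 2, DME = 2)
  d1 <- tempfile("oct1"); d2 <- tempfile("oct2")
  m1 <- make_synthetic_oct(d1, counts, image_size = c(60, 150), seed = 77)
  m2 <- make_synthetic_oct(d2, counts, image_size = c(60, 150), seed = 77)
  expect_equal(nrow(m1$records), 10)
  expect_equal(manifest_counts(m1)$total, rep(2, 5))
  for (i in seq_len(nrow(m1$records))) {
    expect_identical(readBin(m1$records$path[i], "raw", 1e6),
                     readBin(m2$records$path[i], "raw", 1e6))
  }
  expect_error(make_synthetic_oct(tempfile(), c(ARMD = 0, DME = 2)),
               "positive")
})

test_that("default class counts scale the reference distribution down 20x", {
  counts <- octaco:::.oct_default_counts()
  expect_identical(unname(counts), c(37L, 22L, 16L, 37L, 38L))
  expect_equal(sum(counts), 150)
})

test_that("emulated geometry falls in the stated height and width ranges", {
  d <- tempfile("octgeo")
  m <- make_synthetic_oct(d, c(ARMD = 2, DME = 2), seed = 5)
  for (p in m$records$path) {
    img <- read_oct_image(p)
    expect_true(nrow(img) >= 300 && nrow(img) <= 350)
    expect_true(ncol(img) >= 1000 && ncol(img) <= 1050)
  }
})
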