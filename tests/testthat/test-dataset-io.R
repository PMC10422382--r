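test_that("scan_dataset builds a deterministic manifest from a class tree", {
  root <- noise_tree(paste0("c", 1:5), 4)
  m <- scan_dataset(root)
  expect_s3_class(m, "image_manifest")
  expect_equal(nrow(m$records), 20)
  expect_equal(m$class_names, paste0("c", 1:5))
  expect_equal(m$records$path, sort(m$records$path))
  expect_true(all(m$records$split == "unassigned"))
})

test_that("scan_dataset skips non-image files with a warning and rejects bad trees", {
  root <- noise_tree(c("a", "b"), 3)
  writeLines("not an image", file.path(root, "a", "readme.txt"))
  expect_warning(m <- scan_dataset(root), "non-image")
  expect_equal(nrow(m$records), 6)

  expect_error(suppressWarnings(
    scan_dataset(root, class_names = c("a", "b", "missing"))), "missing")
  empty <- tempfile()
  dir.create(file.path(empty, "only"), recursive = TRUE)
  expect_error(scan_dataset(empty, class_names = "only"), "no images")
})

test_that("stratified split reproduces the reference per-class arithmetic", {
  counts <- c(ARMD = 738, BRVO = 440, CRVO = 313, CSCR = 748, DME = 759)
  root <- placeholder_tree(counts)
  m <- scan_dataset(root, class_names = names(counts))
  expect_equal(nrow(m$records), 2998)
  sp <- split_manifest(m, test_fraction = 0.2, seed = 5)
  tab <- manifest_counts(sp)
  expect_equal(tab$test, c(148, 88, 63, 150, 152))
  expect_equal(tab$train, c(590, 352, 250, 598, 607))
  expect_equal(tab$test + tab$train, tab$total)
})

test_that("round_half_up rounds .5 upward, unlike banker's rounding", {
  expect_equal(round_half_up(c(147.6, 62.6, 149.6, 151.8)),
               c(148, 63, 150, 152))
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
})

test_that("split selection is uniform-seeded and reproducible", {
  root <- noise_tree(c("x", "y"), 10)
  m <- scan_dataset(root)
  s1 <- split_manifest(m, 0.2, seed = 9)
  s2 <- split_manifest(m, 0.2, seed = 9)
  s3 <- split_manifest(m, 0.2, seed = 10)
  expect_identical(s1$records, s2$records)
  expect_false(identical(s1$records$split, s3$records$split))
  # disjoint and exhaustive partition
  expect_true(all(s1$records$split %in% c("train", "test")))
})

test_that("degenerate split requests are rejected", {
  root <- noise_tree(c("x", "y"), 10)
  m <- scan_dataset(root)
  expect_error(split_manifest(m, 0.0), "strictly inside")
  expect_error(split_manifest(m, 1.0), "strictly inside")
  tiny <- noise_tree("solo", 1)
  expect_error(split_manifest(scan_dataset(tiny), 0.2), "at least 2")
  s <- split_manifest(m, 0.2)
  expect_error(split_manifest(s, 0.2), "already carries")
})

test_that("manifest round-trips through its delimited format", {
  root <- noise_tree(c("a", "b"), 3)
  m <- split_manifest(scan_dataset(root), 0.34, seed = 1)
  p <- tempfile(fileext = ".csv")
  write_manifest(m, p)
  m2 <- read_manifest(p)
  expect_identical(m$records, m2$records)
  expect_identical(m$class_names, m2$class_names)
})
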