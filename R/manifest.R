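#' Image dataset manifests and the stratified 80:20 split
#'
#' An `image_manifest` records one row per image of a directory-per-class
#' dataset (`root/<class>/<image>`), with its class label and train/test
#' split assignment.
#'
#' @name manifest
NULL

.image_exts <- c("png", "jpg", "jpeg", "tif", "tiff")

new_manifest <- function(records, class_names) {
  stopifnot(is.data.frame(records),
            all(c("path", "class_name", "split") %in% names(records)))
  bad <- setdiff(unique(records$class_name), class_names)
  if (length(bad))
    stop("manifest records carry unknown class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(records = records, class_names = class_names),
            class = "image_manifest")
}

#' Scan a directory-per-class image dataset
#'
#' Expects one subdirectory of `root` per class name, each holding image
#' files (png/jpg/jpeg/tif/tiff, case-insensitive). Other files are skipped
#' with a warning. Records are ordered lexicographically by path so the
#' manifest is deterministic.
#'
#' @param root dataset root directory.
#' @param class_names ordered character vector of class labels; defaults to
#'   the sorted subdirectory names of `root`.
#' @return an `image_manifest` with all records unassigned.
#' @export
scan_dataset <- function(root, class_names = NULL) {
  if (!dir.exists(root)) stop("dataset root not found: ", root, call. = FALSE)
  if (is.null(class_names)) {
    class_names <- sort(basename(list.dirs(root, recursive = FALSE)))
    if (!length(class_names)) stop("no class subdirectories in ", root, call. = FALSE)
  }
  recs <- list()
  for (cl in class_names) {
    d <- file.path(root, cl)
    if (!dir.exists(d))
      stop("missing class directory: ", d, call. = FALSE)
    files <- sort(list.files(d, full.names = TRUE, no.. = TRUE))
    files <- files[!dir.exists(files)]
    is_img <- tolower(tools::file_ext(files)) %in% .image_exts
    if (any(!is_img))
      warning("skipping ", sum(!is_img), " non-image file(s) in ", d,
              call. = FALSE)
    files <- files[is_img]
    if (!length(files)) stop("class directory has no images: ", d, call. = FALSE)
    recs[[cl]] <- data.frame(path = files, class_name = cl,
                             split = "unassigned", stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$path), , drop = FALSE]
  rownames(records) <- NULL
  new_manifest(records, class_names)
}

#' Stratified train/test split of a manifest
#'
#' Assigns each record to `train` or `test`. Per class, the test count is
#' `round_half_up(test_fraction * class_total)` — the rounding rule that
#' reproduces the reference per-class test/train tallies (e.g. 738 images
#' at 20\% give 148 test / 590 train). Selection of which images land in
#' the test set is uniform at random under `seed`.
#'
#' @param m an `image_manifest` with all records unassigned.
#' @param test_fraction test proportion, strictly inside (0, 1); default 0.2.
#' @param seed integer RNG seed.
#' @param stratified logical; stratified per-class selection (default TRUE).
#'   When FALSE the total test count is still `round_half_up` of the grand
#'   total and selection ignores class.
#' @return the manifest with `split` filled in.
#' @export
split_manifest <- function(m, test_fraction = 0.2, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(m, "image_manifest"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie strictly inside (0, 1)", call. = FALSE)
  if (any(m$records$split != "unassigned"))
    stop("manifest already carries split assignments", call. = FALSE)
  rec <- m$records
  counts <- table(factor(rec$class_name, levels = m$class_names))
  if (any(counts < 2))
    stop("every class needs at least 2 images to split; offending class(es): ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  rec$split <- "train"
  with_seed(as.integer(seed), {
    if (stratified) {
      for (cl in m$class_names) {
        idx <- which(rec$class_name == cl)
        n_test <- as.integer(round_half_up(test_fraction * length(idx)))
        if (n_test > 0) rec$split[sample(idx, n_test)] <- "test"
      }
    } else {
      n_test <- as.integer(round_half_up(test_fraction * nrow(rec)))
      if (n_test > 0) rec$split[sample(nrow(rec), n_test)] <- "test"
    }
  })
  new_manifest(rec, m$class_names)
}

#' Per-class split tallies of a manifest
#'
#' @param m an `image_manifest`.
#' @return data.frame with columns class, total, test, train.
#' @export
manifest_counts <- function(m) {
  stopifnot(inherits(m, "image_manifest"))
  out <- data.frame(class = m$class_names)
  f <- factor(m$records$class_name, levels = m$class_names)
  out$total <- as.integer(table(f))
  out$test <- as.integer(table(f[m$records$split == "test"]))
  out$train <- as.integer(table(f[m$records$split == "train"]))
  out
}

#' @export
print.image_manifest <- function(x, ...) {
  cat("Image manifest:", nrow(x$records), "images,",
      length(x$class_names), "classes\n")
  print(manifest_counts(x))
  invisible(x)
}

#' Write / read a manifest as a delimited table
#'
#' Plain UTF-8 CSV with header `path,class_name,split`, one row per image.
#'
#' @param m an `image_manifest`.
#' @param path output file.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns an `image_manifest`.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "image_manifest"))
  data.table::fwrite(m$records, path)
  invisible(path)
}

#' @rdname write_manifest
#' @param class_names optional ordered class labels; defaults to sorted
#'   unique labels present in the file.
#' @export
read_manifest <- function(path, class_names = NULL) {
  rec <- as.data.frame(data.table::fread(path, colClasses = "character"))
  new_manifest(rec, class_names %||% sort(unique(rec$class_name)))
}
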