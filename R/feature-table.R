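#' Deep feature tables
#'
#' A `feature_table` holds an N x d matrix of deep features (rows = images,
#' columns = features), integer class labels (1-based indices into
#' `class_names`), and provenance describing which backbone and layer
#' produced the features.
#'
#' @param x numeric N x d matrix, no missing values.
#' @param labels integer vector of length N.
#' @param class_names character vector of class labels; `labels` index it.
#' @param provenance named list (backbone, feature_layer, fingerprint, ...).
#' @return a `feature_table`.
#' @export
feature_table <- function(x, labels, class_names = NULL, provenance = list()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  assert_that(nrow(x) == length(labels),
              "feature matrix rows must match label length")
  assert_that(!anyNA(x) && all(is.finite(x)),
              "feature table must not contain missing or non-finite values")
  if (is.null(class_names)) class_names <- as.character(sort(unique(labels)))
  assert_that(all(labels >= 1L & labels <= length(class_names)),
              "labels must index class_names")
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  structure(list(matrix = x, labels = labels, class_names = class_names,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features, %d classes",
              nrow(x$matrix), ncol(x$matrix), length(x$class_names)))
  if (!is.null(x$provenance$backbone))
    cat(sprintf(" [%s/%s]", x$provenance$backbone,
                x$provenance$feature_layer %||% "?"))
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' Write a feature table to disk
#'
#' Delimited CSV with header `label,f0001..f<d>`, first column the integer
#' class label; a sidecar `<path>.meta.json` records class names and
#' provenance. The round trip through [read_feature_table()] is exact:
#' feature values are written as full-precision decimal.
#'
#' @param ft a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.table::data.table(label = ft$labels)
  # %.17g guarantees an exact double round trip (fwrite's 15 digits do not)
  chr <- sprintf("%.17g", ft$matrix)
  dim(chr) <- dim(ft$matrix)
  colnames(chr) <- sprintf("f%04d", seq_len(ncol(chr)))
  df <- cbind(df, data.table::as.data.table(chr))
  data.table::fwrite(df, path, quote = FALSE)
  meta <- list(class_names = ft$class_names, provenance = ft$provenance,
               n = nrow(ft$matrix), d = ncol(ft$matrix))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- data.table::fread(path)
  assert_that(names(df)[1] == "label", "first column must be 'label'")
  labels <- as.integer(df$label)
  mat <- as.matrix(df[, -1, drop = FALSE])
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  cls <- unlist(meta$class_names) %||% as.character(sort(unique(labels)))
  feature_table(mat, labels, class_names = cls,
                provenance = lapply(meta$provenance %||% list(), unlist))
}

#' Restrict a feature table to a column subset
#'
#' @param ft a `feature_table`.
#' @param subset integer feature (column) indices to keep.
#' @return a `feature_table` over the selected columns; provenance gains a
#'   `selected_from` entry.
#' @export
subset_features <- function(ft, subset) {
  stopifnot(inherits(ft, "feature_table"))
  subset <- as.integer(subset)
  assert_that(all(subset >= 1L & subset <= ncol(ft$matrix)),
              "feature subset references out-of-range column indices")
  prov <- ft$provenance
  prov$selected_from <- ncol(ft$matrix)
  feature_table(ft$matrix[, subset, drop = FALSE], ft$labels,
                ft$class_names, prov)
}
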