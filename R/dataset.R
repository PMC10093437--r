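#' Construct a classification dataset
#'
#' The container every validation routine consumes: a numeric feature matrix,
#' a label factor, and a vector of stable sample identifiers. Identifiers are
#' the currency of error sets — a sample keeps its id through shuffling, fold
#' assignment and down-sampling, so error sets from different repetitions can
#' be intersected meaningfully.
#'
#' @param features numeric matrix or data frame, one row per sample.
#' @param labels vector coercible to factor, one label per sample; at least
#'   two distinct values, no missing entries.
#' @param ids optional integer vector of unique sample identifiers; defaults
#'   to `0:(N-1)` so ids double as stable row positions.
#' @return an object of class `ec_dataset` with elements `features`, `labels`
#'   and `ids`.
#' @examples
#' ds <- ec_dataset(matrix(rnorm(20), 10), rep(c("a", "b"), 5))
#' ds
#' @export
ec_dataset <- function(features, labels, ids = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop_invalid("features must be a numeric matrix or all-numeric data frame")
  n <- nrow(features)
  if (length(labels) != n)
    stop_invalid("labels length (%d) does not match feature rows (%d)",
                 length(labels), n)
  if (anyNA(labels)) stop_invalid("labels contain missing values")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    stop_invalid("at least 2 distinct label values are required, found %d",
                 nlevels(labels))
  if (is.null(ids)) ids <- seq_len(n) - 1L
  ids <- as.integer(ids)
  if (length(ids) != n) stop_invalid("ids length does not match feature rows")
  if (anyNA(ids)) stop_invalid("ids contain missing values")
  if (anyDuplicated(ids)) stop_invalid("ids must be unique")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  structure(list(features = features, labels = labels, ids = ids),
            class = "ec_dataset")
}

#' @export
print.ec_dataset <- function(x, ...) {
  cat(sprintf("<ec_dataset> %d samples x %d features, %d classes (%s)\n",
              nrow(x$features), ncol(x$features), nlevels(x$labels),
              paste(utils::head(table(x$labels), 6), collapse = "/")))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds an [ec_dataset()].
#' @return integer sample count.
#' @export
n_samples <- function(ds) {
  stopifnot(inherits(ds, "ec_dataset"))
  nrow(ds$features)
}

# Row-subset a dataset by position, preserving ids and any synthetic metadata.
subset_dataset <- function(ds, idx) {
  out <- ec_dataset(ds$features[idx, , drop = FALSE],
                    ds$labels[idx], ds$ids[idx])
  attr(out, "synthetic_spec") <- attr(ds, "synthetic_spec")
  out
}

#' Read a classification dataset from CSV
#'
#' Expects a header row, one numeric column per feature, and a label column.
#' When no id column is named, ids `0..N-1` are assigned in row order; an
#' explicit id column is preserved verbatim.
#'
#' @param path CSV file path.
#' @param label_column name of the label column.
#' @param id_column optional name of an integer id column.
#' @return an [ec_dataset()].
#' @export
read_dataset <- function(path, label_column, id_column = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df))
    stop_invalid("label column '%s' not found in %s", label_column, path)
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df))
      stop_invalid("id column '%s' not found in %s", id_column, path)
    ids <- df[[id_column]]
    if (anyDuplicated(ids)) stop_invalid("duplicate ids in column '%s'", id_column)
  }
  feat_cols <- setdiff(names(df), c(label_column, id_column))
  if (length(feat_cols) == 0) stop_invalid("no feature columns found")
  non_num <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
  if (length(non_num) > 0)
    stop_invalid("non-numeric feature column(s): %s",
                 paste(non_num, collapse = ", "))
  ec_dataset(as.matrix(df[feat_cols]), df[[label_column]], ids)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: feature columns, a `label` column and a
#' `sample_id` column, row order preserved.
#'
#' @param ds an [ec_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "ec_dataset"))
  df <- data.frame(ds$features, check.names = FALSE)
  df$label <- as.character(ds$labels)
  df$sample_id <- ds$ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
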