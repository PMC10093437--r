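# K-fold planning and train/validation splitting. Stratification is on by
# default: per-class fold sizes differ by at most one, which keeps small or
# imbalanced classes represented in every fold.

#' Plan a K-fold partition
#'
#' Assigns each sample to one of `K` folds. Under stratification the
#' assignment balances every class separately (per-class fold counts differ
#' by at most 1); otherwise overall fold sizes differ by at most 1. The plan
#' is deterministic given `seed`.
#'
#' @param ds an [ec_dataset()].
#' @param K number of folds, at least 2.
#' @param seed integer seed for the shuffle; `NULL` uses the current RNG
#'   state.
#' @param stratified balance folds within each class (default `TRUE`).
#' @return integer vector of fold indices in `1..K`, one per sample.
#' @export
plan_folds <- function(ds, K, seed = NULL, stratified = TRUE) {
  stopifnot(inherits(ds, "ec_dataset"))
  K <- as.integer(K)
  if (K < 2) stop_invalid("K must be at least 2")
  n <- n_samples(ds)
  if (n < K) stop_invalid("cannot split %d samples into %d folds", n, K)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in levels(ds$labels)) {
      idx <- which(ds$labels == cl)
      if (length(idx) < K)
        stop_invalid("class '%s' has %d samples, fewer than K = %d required for stratified folds",
                     cl, length(idx), K)
      # random fold order for the remainder, then shuffle sample order
      folds[sample(idx)] <- rep(sample.int(K), length.out = length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep(sample.int(K), length.out = n)
  }
  folds
}

#' Split a dataset into training and validation parts
#'
#' Supports the external validation approach when only a single dataset is
#' available: holds out a `fraction` of samples as the validation set,
#' preserving class proportions within one sample per class when stratified.
#' Deterministic given `seed`.
#'
#' @param ds an [ec_dataset()].
#' @param fraction validation fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @param stratified sample within classes (default `TRUE`).
#' @return list with elements `train` and `val`, both [ec_dataset()]s with
#'   disjoint ids.
#' @export
split_validation <- function(ds, fraction, seed = NULL, stratified = TRUE) {
  stopifnot(inherits(ds, "ec_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    stop_invalid("fraction must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(ds)
  if (stratified) {
    val_idx <- unlist(lapply(levels(ds$labels), function(cl) {
      idx <- which(ds$labels == cl)
      k <- round(fraction * length(idx))
      if (k == 0 || k == length(idx))
        stop_invalid("fraction %.3f leaves class '%s' empty on one side of the split",
                     fraction, cl)
      sample(idx, k)
    }))
  } else {
    k <- round(fraction * n)
    if (k == 0 || k == n)
      stop_invalid("fraction %.3f yields an empty train or validation part", fraction)
    val_idx <- sample.int(n, k)
  }
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_len(n), val_idx)
  list(train = subset_dataset(ds, train_idx),
       val = subset_dataset(ds, val_idx))
}
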