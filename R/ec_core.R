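# Core error-consistency statistic: Jaccard overlap of sample-wise error
# sets, the pairwise matrix over a collection of sets, and its mean/SD
# summary. Undefined values (both sets empty) are NA throughout and are
# propagated, never dropped, until summarize_ec() separates them out.

#' Construct an error set
#'
#' An error set records which held-out samples a trained model misclassified,
#' identified by sample id, together with its provenance: which validation
#' repetition produced it and which model within the repetition (the fold
#' index under the external approach; 1 for the per-repetition master set of
#' the internal approach).
#'
#' @param members integer ids of misclassified samples (subset of `support`).
#' @param repetition 1-based repetition index.
#' @param model_index 1-based model index within the repetition.
#' @param support integer ids of all samples on which predictions were made;
#'   must be non-empty.
#' @return an object of class `error_set`.
#' @export
error_set <- function(members, repetition = 1L, model_index = 1L, support) {
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0) stop_invalid("error set support must be non-empty")
  members <- sort(unique(as.integer(members)))
  if (!all(members %in% support))
    stop_invalid("error set members must be a subset of its support")
  structure(list(members = members,
                 repetition = as.integer(repetition),
                 model_index = as.integer(model_index),
                 support = support),
            class = "error_set")
}

#' @export
print.error_set <- function(x, ...) {
  cat(sprintf("<error_set> repetition %d, model %d: %d/%d samples in error\n",
              x$repetition, x$model_index, length(x$members), length(x$support)))
  invisible(x)
}

as_members <- function(x) {
  if (inherits(x, "error_set")) x$members else sort(unique(as.integer(x)))
}

#' Error consistency between two error sets
#'
#' The size of the intersection of the two member sets divided by the size of
#' their union (the Jaccard index over sample ids). When both sets are empty
#' — a pair of perfect classifiers — there are no errors upon which to be
#' consistent and the statistic is undefined, returned as `NA`.
#'
#' @param a,b [error_set()] objects, or plain integer vectors of member ids.
#' @return a value in `[0, 1]`, or `NA` when both member sets are empty.
#' @examples
#' error_consistency(c(1, 2), c(2, 3))   # 1/3
#' error_consistency(integer(0), integer(0))  # NA: nothing to be consistent on
#' @export
error_consistency <- function(a, b) {
  a <- as_members(a)
  b <- as_members(b)
  u <- length(unique(c(a, b)))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# Pairwise intersection/union sizes for sets encoded as a logical incidence
# matrix (rows = sets, columns = id universe). Returns the upper-triangular
# EC values in lexicographic (i, j) order for the given row block.
ec_block <- function(M, rows, all_rows_from) {
  Mi <- M * 1L
  inter <- tcrossprod(Mi[rows, , drop = FALSE],
                      Mi[all_rows_from, , drop = FALSE])
  sz <- rowSums(Mi)
  uni <- outer(sz[rows], sz[all_rows_from], "+") - inter
  val <- inter / uni           # 0/0 -> NaN, the undefined sentinel
  val[is.nan(val)] <- NA_real_
  val
}

#' Pairwise error-consistency values over a collection of error sets
#'
#' Computes the `n(n-1)/2` upper-triangular entries of the error-consistency
#' matrix (the diagonal is identically 1 and the lower triangle mirrors the
#' upper, so neither is stored). Entries are enumerated in lexicographic
#' `(i, j)` order, `i < j`, for reproducible serialization.
#'
#' For collections larger than `cap` sets the full entry table is not
#' materialized; pair values are streamed block-wise into running moments, and
#' the returned object carries the summary statistics only.
#'
#' @param sets list of [error_set()] objects (or integer member vectors), at
#'   least 2.
#' @param cap largest number of sets for which the entry table is kept
#'   (default 2000, i.e. up to ~2 million stored pairs).
#' @return an object of class `pairwise_ec` with elements `n_sets`, `entries`
#'   (data frame `i`, `j`, `ec`, with `NA` for undefined pairs; `NULL` when
#'   streamed) and pre-accumulated moments used by [summarize_ec()].
#' @export
pairwise_ec <- function(sets, cap = 2000L) {
  if (!is.list(sets) || length(sets) < 2)
    stop_invalid("pairwise error consistency needs at least 2 error sets, got %d",
                 if (is.list(sets)) length(sets) else 1L)
  n <- length(sets)
  members <- lapply(sets, as_members)
  universe <- sort(unique(unlist(members)))
  # Incidence over the ids that occur in any set; absent ids never affect
  # intersections or unions.
  M <- matrix(FALSE, n, max(1L, length(universe)))
  for (r in seq_len(n))
    if (length(members[[r]]) > 0)
      M[r, match(members[[r]], universe)] <- TRUE

  s <- 0; s2 <- 0; n_def <- 0L; n_undef <- 0L
  keep <- n <= cap
  entries <- NULL
  if (keep) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    full <- ec_block(M, seq_len(n), seq_len(n))
    vals <- full[ij]
    entries <- data.frame(i = ij[, 1], j = ij[, 2], ec = vals)
    def <- !is.na(vals)
    s <- sum(vals[def]); s2 <- sum(vals[def]^2)
    n_def <- sum(def); n_undef <- sum(!def)
  } else {
    block <- 256L
    for (start in seq(1L, n - 1L, by = block)) {
      rows <- start:min(start + block - 1L, n - 1L)
      v <- ec_block(M, rows, seq_len(n))
      # keep only j > i within this block of rows
      sel <- outer(rows, seq_len(n), "<")
      vals <- v[sel]
      def <- !is.na(vals)
      s <- s + sum(vals[def]); s2 <- s2 + sum(vals[def]^2)
      n_def <- n_def + sum(def); n_undef <- n_undef + sum(!def)
    }
  }
  structure(list(n_sets = n, entries = entries,
                 sum = s, sumsq = s2,
                 n_pairs_defined = n_def, n_pairs_undefined = n_undef),
            class = "pairwise_ec")
}

#' @export
print.pairwise_ec <- function(x, ...) {
  cat(sprintf("<pairwise_ec> %d sets, %d pairs (%d defined, %d undefined)%s\n",
              x$n_sets, x$n_pairs_defined + x$n_pairs_undefined,
              x$n_pairs_defined, x$n_pairs_undefined,
              if (is.null(x$entries)) " [streamed]" else ""))
  invisible(x)
}

#' Summarize pairwise error consistency
#'
#' Mean (AEC, the average error consistency) and sample standard deviation
#' (denominator `n - 1`) of the defined upper-triangular pair values.
#' Undefined pairs — both error sets empty — are counted and excluded from
#' the moments; a warning is raised when any are present so perfect-classifier
#' degeneracy is never silent.
#'
#' @param pec a [pairwise_ec()] object.
#' @return an object of class `ec_summary` with elements `aec`, `sd`,
#'   `n_pairs_defined`, `n_pairs_undefined`, `n_sets`. `aec` is `NA` iff no
#'   pair is defined.
#' @export
summarize_ec <- function(pec) {
  stopifnot(inherits(pec, "pairwise_ec"))
  nd <- pec$n_pairs_defined
  if (pec$n_pairs_undefined > 0)
    warning(sprintf("%d of %d error-set pairs are undefined (both sets empty); excluded from AEC/SD",
                    pec$n_pairs_undefined, nd + pec$n_pairs_undefined),
            call. = FALSE)
  if (nd == 0) {
    aec <- NA_real_; sdv <- NA_real_
  } else {
    aec <- pec$sum / nd
    sdv <- if (nd > 1) sqrt(max(0, (pec$sumsq - nd * aec^2) / (nd - 1))) else NA_real_
  }
  structure(list(aec = aec, sd = sdv,
                 n_pairs_defined = nd,
                 n_pairs_undefined = pec$n_pairs_undefined,
                 n_sets = pec$n_sets),
            class = "ec_summary")
}

#' @export
print.ec_summary <- function(x, ...) {
  if (is.na(x$aec)) {
    cat(sprintf("<ec_summary> AEC undefined (all %d pairs undefined: perfect classifiers)\n",
                x$n_pairs_undefined))
  } else {
    cat(sprintf("<ec_summary> AEC %.4f (SD %s) over %d defined pairs (%d undefined)\n",
                x$aec, ifelse(is.na(x$sd), "NA", sprintf("%.4f", x$sd)),
                x$n_pairs_defined, x$n_pairs_undefined))
  }
  invisible(x)
}

#' Serialize pairwise error-consistency entries
#'
#' Long format with columns `(i, j, ec)`; undefined values are written as an
#' empty field in CSV and as `null` in JSON. Only available when the entry
#' table was materialized (`n_sets <= cap` at computation time).
#'
#' @param pec a [pairwise_ec()] object with materialized entries.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_pairwise_ec <- function(pec, path, format = c("csv", "json")) {
  stopifnot(inherits(pec, "pairwise_ec"))
  format <- match.arg(format)
  if (is.null(pec$entries))
    stop_invalid("pairwise entries were streamed, not stored; recompute with a larger cap")
  if (format == "csv") {
    utils::write.csv(pec$entries, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(pec$entries, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
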