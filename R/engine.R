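# The two error-consistency-enhanced validation procedures. Both repeat
# K-fold validation m times with independently reshuffled folds. The internal
# approach unites each repetition's K disjoint fold error sets into one
# master error set over all N samples (n = m sets); the external approach
# scores every fold-trained model on a fixed held-out validation set
# (n = m*K sets).

#' Validation configuration
#'
#' Protocol constants for a validation run. The defaults — `K = 5` folds
#' repeated `m = 500` times — follow common practice for statistically
#' reliable repeated cross-validation; small exploratory runs should lower
#' `m`. Folds are stratified by default to keep every class represented in
#' every fold; a flag restores plain shuffling.
#'
#' @param K number of folds (>= 2).
#' @param m number of validation repetitions (>= 1).
#' @param approach `"internal"` (consistency over per-repetition master error
#'   sets) or `"external"` (consistency of each fold model on a held-out
#'   validation set).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param master_seed integer seed from which all per-repetition seeds are
#'   derived (see [derive_seeds()]).
#' @param validation_fraction fraction held out by [split_validation()] when
#'   the external approach is given a single dataset.
#' @param pairwise_cap passed to [pairwise_ec()]; collections larger than
#'   this stream their pair values instead of storing them.
#' @return an object of class `validation_config`.
#' @export
validation_config <- function(K = 5L, m = 500L,
                              approach = c("internal", "external"),
                              stratified = TRUE,
                              master_seed = 1L,
                              validation_fraction = 0.2,
                              pairwise_cap = 2000L) {
  approach <- match.arg(approach)
  K <- as.integer(K); m <- as.integer(m)
  if (K < 2) stop_invalid("K must be at least 2")
  if (m < 1) stop_invalid("m must be at least 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_invalid("validation_fraction must lie strictly between 0 and 1")
  structure(list(K = K, m = m, approach = approach,
                 stratified = isTRUE(stratified),
                 master_seed = as.integer(master_seed),
                 validation_fraction = validation_fraction,
                 pairwise_cap = as.integer(pairwise_cap)),
            class = "validation_config")
}

#' @export
print.validation_config <- function(x, ...) {
  cat(sprintf("<validation_config> %s approach, K = %d, m = %d, %s, seed %d\n",
              x$approach, x$K, x$m,
              if (x$stratified) "stratified" else "unstratified",
              x$master_seed))
  invisible(x)
}

# Fit/predict with classifier failures re-raised with repetition/fold context.
fit_predict <- function(clf, tr_feat, tr_lab, tr_ids, te_feat, te_ids,
                        repetition, fold) {
  ctx <- sprintf("repetition %d, fold %d", repetition, fold)
  model <- tryCatch(clf$fit(tr_feat, tr_lab, tr_ids), error = function(e)
    stop_contract("classifier '%s' failed to fit (%s): %s",
                  clf$descriptor, ctx, conditionMessage(e)))
  pred <- tryCatch(clf$predict(model, te_feat, te_ids), error = function(e)
    stop_contract("classifier '%s' failed to predict (%s): %s",
                  clf$descriptor, ctx, conditionMessage(e)))
  if (length(pred) != nrow(te_feat))
    stop_contract("classifier '%s' returned %d predictions for %d rows (%s)",
                  clf$descriptor, length(pred), nrow(te_feat), ctx)
  list(model = model, pred = pred)
}

new_run_result <- function(...) structure(list(...), class = "run_result")

#' Internal-approach validation: consistency of master error sets
#'
#' Runs `m` repetitions of K-fold cross-validation. In each repetition the
#' folds are freshly reshuffled; each fold model is trained on the other
#' `K - 1` folds and predicts its held-out fold, and the K disjoint fold
#' error sets are united into one master error set covering every sample
#' exactly once. Overall accuracy for the repetition is pooled over all N
#' held-out predictions, so `OA = 1 - |master| / N` holds exactly. Error
#' consistency is then summarized over the `m` master sets.
#'
#' @param ds an [ec_dataset()] with `N >= 2 * K` samples.
#' @param clf a [classifier_adapter()].
#' @param cfg a [validation_config()] with `approach = "internal"`.
#' @return an object of class `run_result`: per-repetition accuracies
#'   (`oa_per_repetition`, `mean_oa`, `sd_oa`), the `m` error sets, the
#'   pairwise consistency values (`pairwise`) and their summary
#'   (`ec_summary`), the configuration echo and the derived seeds.
#' @export
run_internal <- function(ds, clf, cfg = validation_config()) {
  stopifnot(inherits(ds, "ec_dataset"), inherits(clf, "classifier_adapter"))
  if (cfg$approach != "internal")
    stop_invalid("run_internal requires approach = 'internal'")
  n <- n_samples(ds)
  if (n < 2 * cfg$K)
    stop_invalid("need at least 2*K = %d samples, got %d", 2 * cfg$K, n)
  seeds <- derive_seeds(cfg$master_seed, cfg$m)
  sets <- vector("list", cfg$m)
  oa <- numeric(cfg$m)
  for (r in seq_len(cfg$m)) {
    folds <- plan_folds(ds, cfg$K, seed = seeds[r], stratified = cfg$stratified)
    err_ids <- integer(0)
    for (k in seq_len(cfg$K)) {
      tr <- folds != k; te <- folds == k
      fp <- fit_predict(clf, ds$features[tr, , drop = FALSE], ds$labels[tr],
                        ds$ids[tr], ds$features[te, , drop = FALSE],
                        ds$ids[te], r, k)
      wrong <- as.character(fp$pred) != as.character(ds$labels[te])
      err_ids <- c(err_ids, ds$ids[te][wrong])
    }
    sets[[r]] <- error_set(err_ids, repetition = r, model_index = 1L,
                           support = ds$ids)
    oa[r] <- 1 - length(sets[[r]]$members) / n
  }
  pec <- if (cfg$m >= 2) pairwise_ec(sets, cap = cfg$pairwise_cap) else NULL
  summ <- if (!is.null(pec)) suppressWarnings(summarize_ec(pec)) else NULL
  new_run_result(approach = "internal",
                 descriptor = clf$descriptor,
                 n = n,
                 oa_per_repetition = oa,
                 mean_oa = mean(oa), sd_oa = stats::sd(oa),
                 error_sets = sets,
                 pairwise = pec,
                 ec_summary = summ,
                 config = cfg, seeds = seeds)
}

#' External-approach validation: consistency on a held-out validation set
#'
#' Runs `m` repetitions of K-fold cross-validation on the training set; every
#' fold-trained model additionally predicts the entire validation set,
#' yielding `m * K` error sets whose pairwise consistency is summarized.
#' Two accuracy families are reported and named distinctly: the per-repetition
#' fold-test overall accuracy (pooled over the K held-out training folds,
#' `oa_per_repetition`) and each model's validation-set accuracy
#' (`validation_accuracy`, an `m x K` matrix); neither is privileged.
#'
#' @param train,val [ec_dataset()]s sharing the same feature columns, with
#'   disjoint ids.
#' @param clf a [classifier_adapter()].
#' @param cfg a [validation_config()] with `approach = "external"`.
#' @return a `run_result`, as for [run_internal()], with `error_sets` of
#'   length `m * K` (support = all validation ids) plus the
#'   `validation_accuracy` matrix.
#' @export
run_external <- function(train, val, clf, cfg = validation_config(approach = "external")) {
  stopifnot(inherits(train, "ec_dataset"), inherits(val, "ec_dataset"),
            inherits(clf, "classifier_adapter"))
  if (cfg$approach != "external")
    stop_invalid("run_external requires approach = 'external'")
  if (n_samples(val) < 1) stop_invalid("validation set is empty")
  if (!identical(colnames(train$features), colnames(val$features)))
    stop_invalid("train and validation sets have different feature columns")
  if (length(intersect(train$ids, val$ids)) > 0)
    stop_invalid("train and validation ids overlap")
  n_tr <- n_samples(train)
  if (n_tr < 2 * cfg$K)
    stop_invalid("need at least 2*K = %d training samples, got %d", 2 * cfg$K, n_tr)
  n_val <- n_samples(val)
  seeds <- derive_seeds(cfg$master_seed, cfg$m)
  sets <- vector("list", cfg$m * cfg$K)
  oa_fold <- numeric(cfg$m)
  val_acc <- matrix(NA_real_, cfg$m, cfg$K)
  for (r in seq_len(cfg$m)) {
    folds <- plan_folds(train, cfg$K, seed = seeds[r], stratified = cfg$stratified)
    fold_err <- 0L
    for (k in seq_len(cfg$K)) {
      tr <- folds != k; te <- folds == k
      fp <- fit_predict(clf, train$features[tr, , drop = FALSE],
                        train$labels[tr], train$ids[tr],
                        train$features[te, , drop = FALSE], train$ids[te],
                        r, k)
      fold_err <- fold_err +
        sum(as.character(fp$pred) != as.character(train$labels[te]))
      vpred <- tryCatch(clf$predict(fp$model, val$features, val$ids),
                        error = function(e)
        stop_contract("classifier '%s' failed on the validation set (repetition %d, fold %d): %s",
                      clf$descriptor, r, k, conditionMessage(e)))
      verr <- val$ids[as.character(vpred) != as.character(val$labels)]
      es <- error_set(verr, repetition = r, model_index = k, support = val$ids)
      sets[[(r - 1) * cfg$K + k]] <- es
      val_acc[r, k] <- 1 - length(es$members) / n_val
    }
    oa_fold[r] <- 1 - fold_err / n_tr
  }
  pec <- pairwise_ec(sets, cap = cfg$pairwise_cap)
  summ <- suppressWarnings(summarize_ec(pec))
  new_run_result(approach = "external",
                 descriptor = clf$descriptor,
                 n = n_tr, n_val = n_val,
                 oa_per_repetition = oa_fold,
                 mean_oa = mean(oa_fold), sd_oa = stats::sd(oa_fold),
                 validation_accuracy = val_acc,
                 mean_validation_accuracy = mean(val_acc),
                 error_sets = sets,
                 pairwise = pec,
                 ec_summary = summ,
                 config = cfg, seeds = seeds)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s approach, %s, m = %d, K = %d\n",
              x$approach, x$descriptor, x$config$m, x$config$K))
  cat(sprintf("  mean OA %.4f (SD %s) over %d repetitions\n",
              x$mean_oa, ifelse(is.na(x$sd_oa), "NA", sprintf("%.4f", x$sd_oa)),
              x$config$m))
  if (!is.null(x$ec_summary)) print(x$ec_summary)
  invisible(x)
}
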