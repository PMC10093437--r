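# Classifier adapter contract consumed by the validation engine, preset
# wrappers around standard learners, and deterministic mock classifiers whose
# error sets are known by construction (the test oracles for consistency).

#' Define a classifier adapter
#'
#' The uniform surface the validation engine trains and queries. `fit` is
#' called once per fold with the training features, labels and sample ids and
#' must return a fresh fitted state (no state is shared across fits);
#' `predict` receives that state plus the held-out features and ids and must
#' return one label per row. Real learners ignore the ids; the mock
#' classifiers key on them, because error sets are defined over sample
#' identity, not feature values.
#'
#' @param fit `function(features, labels, ids)` returning a fitted model.
#' @param predict `function(model, features, ids)` returning a label vector
#'   of length `nrow(features)` with levels drawn from those seen in `fit`.
#' @param descriptor short name used in reports.
#' @return an object of class `classifier_adapter`.
#' @export
classifier_adapter <- function(fit, predict, descriptor = "custom") {
  if (!is.function(fit))
    stop_contract("classifier adapter requires a fit(features, labels, ids) function")
  if (!is.function(predict))
    stop_contract("classifier adapter requires a predict(model, features, ids) function")
  structure(list(fit = fit, predict = predict,
                 descriptor = as.character(descriptor)[1]),
            class = "classifier_adapter")
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf("<classifier_adapter> %s\n", x$descriptor))
  invisible(x)
}

#' Wrap a fitted-estimator interface as a classifier adapter
#'
#' Convenience wrapper for estimators exposed as a pair of functions in the
#' usual train/predict style. Each engine fit calls `fit_fun` afresh, so
#' repetitions never share trained state.
#'
#' @param fit_fun `function(features, labels)` returning a model object.
#' @param predict_fun `function(model, features)` returning labels.
#' @param descriptor short name used in reports.
#' @return a [classifier_adapter()].
#' @export
wrap_estimator <- function(fit_fun, predict_fun, descriptor = "wrapped") {
  if (!is.function(fit_fun) || !is.function(predict_fun))
    stop_contract("wrap_estimator needs fit(features, labels) and predict(model, features) functions")
  classifier_adapter(
    fit = function(features, labels, ids) fit_fun(features, labels),
    predict = function(model, features, ids) predict_fun(model, features),
    descriptor = descriptor
  )
}

#' Reference learner presets
#'
#' Named presets for the standard comparison learners: an RBF-kernel support
#' vector machine (`"svm-rbf"`, via e1071), a 100-tree random forest
#' (`"rf-100"`, via randomForest), logistic regression (`"logreg"`, binomial
#' [stats::glm()] for two classes, `nnet::multinom` otherwise), and
#' gradient-boosted decision trees (`"boost-dt"`, via xgboost). Presets
#' arrive with plain defaults; hyperparameter tuning is the caller's
#' responsibility and happens before, not inside, validation.
#'
#' @param name preset name.
#' @param ... additional arguments passed to the underlying fitting function.
#' @return a [classifier_adapter()].
#' @export
preset_classifier <- function(name = c("svm-rbf", "rf-100", "logreg", "boost-dt"),
                              ...) {
  name <- match.arg(name)
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop_contract("preset '%s' requires the '%s' package", name, pkg)
  }
  extra <- list(...)
  switch(name,
    "svm-rbf" = {
      need("e1071")
      classifier_adapter(
        fit = function(features, labels, ids)
          do.call(e1071::svm, c(list(x = features, y = labels, kernel = "radial"), extra)),
        predict = function(model, features, ids)
          stats::predict(model, features),
        descriptor = "svm-rbf")
    },
    "rf-100" = {
      need("randomForest")
      classifier_adapter(
        fit = function(features, labels, ids)
          do.call(randomForest::randomForest, c(list(x = features, y = labels, ntree = 100), extra)),
        predict = function(model, features, ids)
          stats::predict(model, features),
        descriptor = "rf-100")
    },
    "logreg" = {
      classifier_adapter(
        fit = function(features, labels, ids) {
          lv <- levels(labels)
          if (length(lv) == 2) {
            df <- data.frame(features, check.names = FALSE)
            df$.y <- labels
            list(kind = "glm", levels = lv,
                 model = stats::glm(.y ~ ., data = df, family = stats::binomial()))
          } else {
            need("nnet")
            df <- data.frame(features, check.names = FALSE)
            df$.y <- labels
            list(kind = "multinom", levels = lv,
                 model = nnet::multinom(.y ~ ., data = df, trace = FALSE))
          }
        },
        predict = function(model, features, ids) {
          df <- data.frame(features, check.names = FALSE)
          if (model$kind == "glm") {
            p <- stats::predict(model$model, df, type = "response")
            factor(model$levels[1L + (p > 0.5)], levels = model$levels)
          } else {
            factor(as.character(stats::predict(model$model, df)),
                   levels = model$levels)
          }
        },
        descriptor = "logreg")
    },
    "boost-dt" = {
      need("xgboost")
      classifier_adapter(
        fit = function(features, labels, ids) {
          lv <- levels(labels)
          y <- as.integer(labels) - 1L
          params <- c(list(max_depth = 3, nthread = 1), extra)
          if (length(lv) == 2) {
            params$objective <- "binary:logistic"
          } else {
            params$objective <- "multi:softmax"
            params$num_class <- length(lv)
          }
          m <- xgboost::xgboost(data = features, label = y, nrounds = 50,
                                params = params, verbose = 0)
          list(model = m, levels = lv)
        },
        predict = function(model, features, ids) {
          p <- stats::predict(model$model, features)
          lv <- model$levels
          if (length(lv) == 2) factor(lv[1L + (p > 0.5)], levels = lv)
          else factor(lv[p + 1L], levels = lv)
        },
        descriptor = "boost-dt")
    })
}

#' Planted-error mock classifier
#'
#' Predicts the true label for every sample except a fixed set of ids, where
#' it predicts a deliberately wrong label. Its behavior is independent of the
#' training data, so on any held-out set `H` its error set is exactly
#' `error_ids` intersected with `H` — making every downstream consistency
#' value exactly predictable (all defined pairwise values are 1 whenever the
#' planted set is hit).
#'
#' @param error_ids integer ids on which to err (may be empty: a perfect
#'   classifier, whose pairwise consistency is undefined everywhere).
#' @param truth an [ec_dataset()] providing the id-to-label ground truth.
#' @return a [classifier_adapter()].
#' @export
planted_error_classifier <- function(error_ids, truth) {
  stopifnot(inherits(truth, "ec_dataset"))
  error_ids <- as.integer(error_ids)
  if (!all(error_ids %in% truth$ids))
    stop_invalid("error_ids must be ids present in the truth dataset")
  lv <- levels(truth$labels)
  lookup <- truth$labels
  names(lookup) <- as.character(truth$ids)
  classifier_adapter(
    fit = function(features, labels, ids) list(),
    predict = function(model, features, ids) {
      true_lab <- lookup[as.character(ids)]
      pred <- factor(as.character(true_lab), levels = lv)
      bad <- ids %in% error_ids
      pred[bad] <- next_level(pred[bad], lv)
      pred
    },
    descriptor = sprintf("planted-error(%d)", length(error_ids))
  )
}

#' Random-error mock classifier
#'
#' At every fit, draws a fresh error set of size `round(error_rate * N)`
#' uniformly without replacement from the id universe (using the engine's
#' seeded RNG stream); predictions then err exactly on the drawn ids. Because
#' successive fits draw independently, this mock realizes the independence
#' baseline: for rate `k/N` the expected pairwise consistency is approximately
#' `k / (2N - k)`.
#'
#' @param error_rate value in `[0, 1]`.
#' @param truth an [ec_dataset()] providing the id universe and ground truth.
#' @return a [classifier_adapter()].
#' @export
random_error_classifier <- function(error_rate, truth) {
  stopifnot(inherits(truth, "ec_dataset"))
  if (error_rate < 0 || error_rate > 1)
    stop_invalid("error_rate must lie in [0, 1]")
  lv <- levels(truth$labels)
  lookup <- truth$labels
  names(lookup) <- as.character(truth$ids)
  universe <- truth$ids
  k <- round(error_rate * length(universe))
  classifier_adapter(
    fit = function(features, labels, ids) {
      list(err = if (k > 0) sample(universe, k) else integer(0))
    },
    predict = function(model, features, ids) {
      true_lab <- lookup[as.character(ids)]
      pred <- factor(as.character(true_lab), levels = lv)
      bad <- ids %in% model$err
      pred[bad] <- next_level(pred[bad], lv)
      pred
    },
    descriptor = sprintf("random-error(%.2f)", error_rate)
  )
}
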