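# Human-readable reporting and machine serialization of run results. The
# human report rounds to presentation precision (integer percentages, one
# decimal on SDs); the machine outputs keep full precision so every report
# number is recomputable from the emitted CSVs alone.

format_metric_cell <- function(mean, sd) {
  if (is.na(mean)) return("NA")
  sprintf("%.0f (%s)", 100 * mean,
          if (is.na(sd)) "NA" else sprintf("%.1f", 100 * sd))
}

#' Render a run report
#'
#' Formats a [run_internal()]/[run_external()] result the way benchmark
#' tables are usually presented: mean overall accuracy and average error
#' consistency as percentages with their standard deviations in parentheses,
#' joined as `"OA (SD)/AEC (SD)"` — e.g. `"75 (0.6)/72 (2.5)"`. An undefined
#' consistency (perfect classifier) renders as `NA` with an explanatory
#' footnote.
#'
#' @param result a `run_result`.
#' @return an object of class `run_report` with elements `oa_cell`,
#'   `aec_cell`, `cell` (the combined string), `lines` (the full text
#'   report) and a `numbers` list carrying the unrounded values.
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "run_result"))
  summ <- result$ec_summary
  oa_cell <- format_metric_cell(result$mean_oa, result$sd_oa)
  aec_cell <- if (is.null(summ)) "NA" else format_metric_cell(summ$aec, summ$sd)
  cell <- paste0(oa_cell, "/", aec_cell)
  lines <- c(
    sprintf("Error-consistency validation report (%s approach)", result$approach),
    sprintf("Classifier: %s", result$descriptor),
    sprintf("Config: K = %d, m = %d, %s, master seed %d",
            result$config$K, result$config$m,
            if (result$config$stratified) "stratified folds" else "unstratified folds",
            result$config$master_seed),
    sprintf("Samples: %d%s", result$n,
            if (!is.null(result$n_val)) sprintf(" train, %d validation", result$n_val) else ""),
    sprintf("Mean OA (SD) / AEC (SD), percentages: %s", cell))
  if (!is.null(summ)) {
    lines <- c(lines,
               sprintf("Pairwise consistency: %d defined, %d undefined of %d pairs",
                       summ$n_pairs_defined, summ$n_pairs_undefined,
                       summ$n_pairs_defined + summ$n_pairs_undefined))
    if (is.na(summ$aec))
      lines <- c(lines,
                 "Note: AEC is NA (perfect classifier): every error-set pair was empty, so there are no errors upon which to be consistent.")
  }
  if (!is.null(result$mean_validation_accuracy))
    lines <- c(lines,
               sprintf("Mean validation-set accuracy: %.4f", result$mean_validation_accuracy))
  structure(list(oa_cell = oa_cell, aec_cell = aec_cell, cell = cell,
                 lines = lines,
                 numbers = list(mean_oa = result$mean_oa, sd_oa = result$sd_oa,
                                aec = if (is.null(summ)) NA_real_ else summ$aec,
                                aec_sd = if (is.null(summ)) NA_real_ else summ$sd,
                                n_pairs_undefined = if (is.null(summ)) NA_integer_ else summ$n_pairs_undefined)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(x$lines, collapse = "\n"), "\n")
  invisible(x)
}

#' Write machine-readable run outputs
#'
#' Emits deterministic (timestamp-free) artifacts into `dir`:
#' `summary.json` (config echo, seeds, accuracy and consistency summaries),
#' `oa_per_repetition.csv`, `error_sets.csv` (long format: repetition,
#' model_index, sample_id), `pairwise_ec.csv` when the pair table was
#' materialized, and `validation_accuracy.csv` for external runs. Identical
#' runs produce byte-identical files.
#'
#' @param result a `run_result`.
#' @param dir output directory, created if missing.
#' @return character vector of written paths, invisibly.
#' @export
write_run_result <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summ <- result$ec_summary
  summary_obj <- list(
    approach = result$approach,
    classifier = result$descriptor,
    n = result$n,
    config = list(K = result$config$K, m = result$config$m,
                  stratified = result$config$stratified,
                  master_seed = result$config$master_seed),
    seeds = result$seeds,
    mean_oa = result$mean_oa, sd_oa = result$sd_oa,
    aec = if (is.null(summ)) NULL else summ$aec,
    aec_sd = if (is.null(summ)) NULL else summ$sd,
    n_pairs_defined = if (is.null(summ)) NULL else summ$n_pairs_defined,
    n_pairs_undefined = if (is.null(summ)) NULL else summ$n_pairs_undefined,
    table_cell = render_report(result)$cell)
  if (!is.null(result$n_val)) summary_obj$n_val <- result$n_val
  if (!is.null(result$mean_validation_accuracy))
    summary_obj$mean_validation_accuracy <- result$mean_validation_accuracy
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary_obj, p, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  paths <- c(paths, p)

  p <- file.path(dir, "oa_per_repetition.csv")
  utils::write.csv(data.frame(repetition = seq_along(result$oa_per_repetition),
                              oa = result$oa_per_repetition),
                   p, row.names = FALSE)
  paths <- c(paths, p)

  es <- do.call(rbind, lapply(result$error_sets, function(s) {
    if (length(s$members) == 0) return(NULL)
    data.frame(repetition = s$repetition, model_index = s$model_index,
               sample_id = s$members)
  }))
  if (is.null(es))
    es <- data.frame(repetition = integer(0), model_index = integer(0),
                     sample_id = integer(0))
  p <- file.path(dir, "error_sets.csv")
  utils::write.csv(es, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(result$pairwise) && !is.null(result$pairwise$entries)) {
    p <- file.path(dir, "pairwise_ec.csv")
    write_pairwise_ec(result$pairwise, p, "csv")
    paths <- c(paths, p)
  }
  if (!is.null(result$validation_accuracy)) {
    va <- result$validation_accuracy
    p <- file.path(dir, "validation_accuracy.csv")
    utils::write.csv(data.frame(repetition = rep(seq_len(nrow(va)), ncol(va)),
                                model_index = rep(seq_len(ncol(va)), each = nrow(va)),
                                validation_accuracy = as.vector(va)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
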