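# Effect-of-sample-size analysis: random down-sampling to a grid of
# proportions, a full consistency-enhanced validation run per subsample,
# locally weighted trend lines, and bootstrapped rolling-window correlations
# of accuracy/consistency against sample-size percentage.

#' Down-sampling experiment
#'
#' For each proportion and draw, takes one stratified random subsample
#' without replacement and runs [run_internal()] on it, recording the run's
#' mean overall accuracy and average error consistency. A rising profile on
#' the right of the resulting curve suggests that more samples would still
#' improve the metric. Each point consumes its own derived seed, so the whole
#' experiment is deterministic given `cfg$master_seed`, and the point at
#' proportion 1.0 reproduces a plain [run_internal()] on the full dataset
#' under the point's seed.
#'
#' Points whose realized subsample is too small for `2 * K` folds are skipped
#' with a warning rather than failing the experiment. An undefined average
#' consistency (a perfect classifier on that subsample) is carried as `NA`.
#'
#' @param ds an [ec_dataset()].
#' @param clf a [classifier_adapter()].
#' @param proportions grid of subsample proportions in (0, 1].
#' @param draws_per_proportion independent subsample draws per proportion.
#' @param cfg a [validation_config()]; a reduced `m` (e.g. 25-50) keeps the
#'   experiment desk-scale and is recorded in the output.
#' @return a data frame of class `downsampling_points` with columns
#'   `proportion`, `draw`, `realized_n`, `oa`, `oa_sd`, `aec`, `aec_sd`,
#'   `n_pairs_undefined`, `seed`.
#' @export
downsample_experiment <- function(ds, clf, proportions = seq(0.2, 1, by = 0.1),
                                  draws_per_proportion = 10L,
                                  cfg = validation_config(m = 50L)) {
  stopifnot(inherits(ds, "ec_dataset"), inherits(clf, "classifier_adapter"))
  if (any(proportions <= 0 | proportions > 1))
    stop_invalid("proportions must lie in (0, 1]")
  if (cfg$approach != "internal")
    stop_invalid("the down-sampling experiment uses the internal approach")
  grid <- expand.grid(draw = seq_len(draws_per_proportion),
                      proportion = proportions)
  seeds <- derive_seeds(cfg$master_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- grid$proportion[g]
    set.seed(seeds[g])
    idx <- if (p == 1) seq_len(n_samples(ds)) else {
      sort(unlist(lapply(levels(ds$labels), function(cl) {
        cl_idx <- which(ds$labels == cl)
        sample(cl_idx, round(p * length(cl_idx)))
      })))
    }
    realized_n <- length(idx)
    if (realized_n < 2 * cfg$K ||
        any(table(ds$labels[idx]) < cfg$K)) {
      warning(sprintf("skipping proportion %.2f draw %d: %d samples cannot support K = %d stratified folds",
                      p, grid$draw[g], realized_n, cfg$K), call. = FALSE)
      next
    }
    sub_cfg <- cfg
    sub_cfg$master_seed <- seeds[g]
    res <- run_internal(subset_dataset(ds, idx), clf, sub_cfg)
    rows[[g]] <- data.frame(proportion = p, draw = grid$draw[g],
                            realized_n = realized_n,
                            oa = res$mean_oa, oa_sd = res$sd_oa,
                            aec = res$ec_summary$aec,
                            aec_sd = res$ec_summary$sd,
                            n_pairs_undefined = res$ec_summary$n_pairs_undefined,
                            seed = seeds[g])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("downsampling_points", "data.frame")
  out
}

#' Locally weighted trend through down-sampling points
#'
#' Cleveland-style locally weighted regression ([stats::lowess()]) of overall
#' accuracy and of average error consistency against proportion. Points with
#' undefined consistency are excluded from the consistency fit; the
#' consistency trend is then interpolated back onto the full proportion grid
#' (`NA` outside the defined range), so both trends share one x vector.
#'
#' @param points a `downsampling_points` data frame.
#' @param span smoother span (fraction of points in each local fit).
#' @return an object of class `trend_curve`: `x` (sorted proportions),
#'   `y_oa`, `y_aec`, `span`.
#' @export
fit_trend <- function(points, span = 0.75) {
  stopifnot(is.data.frame(points))
  if (sum(!is.na(points$oa)) < 5)
    stop_invalid("need at least 5 points with defined accuracy to fit a trend")
  if (sum(!is.na(points$aec)) < 5)
    stop_invalid("need at least 5 points with defined consistency to fit a trend")
  ord <- order(points$proportion)
  x <- points$proportion[ord]
  lo_oa <- stats::lowess(x, points$oa[ord], f = span)
  def <- !is.na(points$aec[ord])
  lo_aec <- stats::lowess(x[def], points$aec[ord][def], f = span)
  y_aec <- stats::approx(lo_aec$x, lo_aec$y, xout = x, ties = mean,
                         rule = 1)$y
  structure(list(x = x, y_oa = lo_oa$y, y_aec = y_aec, span = span),
            class = "trend_curve")
}

#' Bootstrapped rolling-window correlation
#'
#' Sorts the (sample-size percentage, metric) pairs by percentage, slides a
#' window of `window_size` consecutive pairs, and computes the correlation
#' between percentage and metric within each window. A percentile bootstrap
#' (resampling pairs within the window) supplies a confidence interval per
#' window. Windows in which either variable is constant have undefined
#' correlation and are reported as `NA` without error.
#'
#' @param pairs data frame whose first column is the sample-size percentage
#'   and second column the metric value (any further columns are ignored).
#' @param window_size number of consecutive pairs per window (>= 3).
#' @param n_boot bootstrap draws per window.
#' @param seed integer seed for the bootstrap.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param conf confidence level for the percentile interval.
#' @return an object of class `rolling_correlation`: a data frame with
#'   columns `window`, `center`, `correlation`, `ci_low`, `ci_high`, plus
#'   attributes `window_size`, `n_boot`, `method`.
#' @export
rolling_correlation <- function(pairs, window_size, n_boot = 500L, seed = 1L,
                                method = c("pearson", "spearman"),
                                conf = 0.95) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
  n <- nrow(pairs)
  if (window_size < 3) stop_invalid("window_size must be at least 3")
  if (window_size > n)
    stop_invalid("window_size (%d) exceeds the number of pairs (%d)",
                 window_size, n)
  ord <- order(pairs[[1]])
  x <- as.numeric(pairs[[1]])[ord]
  y <- as.numeric(pairs[[2]])[ord]
  seeds <- derive_seeds(seed, n - window_size + 1L)
  alpha <- (1 - conf) / 2
  rows <- lapply(seq_len(n - window_size + 1L), function(w) {
    wi <- w:(w + window_size - 1L)
    wx <- x[wi]; wy <- y[wi]
    if (stats::sd(wx) == 0 || stats::sd(wy) == 0 ||
        anyNA(wx) || anyNA(wy)) {
      return(data.frame(window = w, center = mean(wx),
                        correlation = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    r <- stats::cor(wx, wy, method = method)
    set.seed(seeds[w])
    boots <- vapply(seq_len(n_boot), function(b) {
      bi <- sample.int(window_size, replace = TRUE)
      bx <- wx[bi]; by <- wy[bi]
      if (stats::sd(bx) == 0 || stats::sd(by) == 0) NA_real_
      else stats::cor(bx, by, method = method)
    }, numeric(1))
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    data.frame(window = w, center = mean(wx), correlation = r,
               ci_low = qs[1], ci_high = qs[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("rolling_correlation", "data.frame"),
            window_size = as.integer(window_size),
            n_boot = as.integer(n_boot), method = method)
}
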