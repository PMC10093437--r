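test_that("the full-proportion point reproduces a plain internal run under its seed", {
  ds <- tiny_dataset(80, seed = 12)
  clf <- planted_error_classifier(c(2L, 4L, 6L), ds)
  cfg <- validation_config(m = 6, master_seed = 77)
  pts <- downsample_experiment(ds, clf, proportions = 1.0,
                               draws_per_proportion = 1, cfg = cfg)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$realized_n, 80)
  ref_cfg <- cfg
  ref_cfg$master_seed <- pts$seed[1]
  ref <- run_internal(ds, clf, ref_cfg)
  expect_identical(pts$oa[1], ref$mean_oa)
  expect_identical(pts$aec[1], ref$ec_summary$aec)
})

test_that("planted-error points have consistency 1 wherever the planted set is hit", {
  ds <- tiny_dataset(100, seed = 13)
  clf <- planted_error_classifier(c(0L, 50L), ds)
  pts <- downsample_experiment(ds, clf, proportions = c(0.3, 0.6, 1.0),
                               draws_per_proportion = 2,
                               cfg = validation_config(m = 4, master_seed = 3))
  expect_true(all(is.na(pts$aec) | pts$aec == 1))
  # realized sizes follow the stratified rounding of the proportion
  expect_true(all(abs(pts$realized_n - round(pts$proportion * 100)) <= 1))
})

test_that("subsampling never duplicates a sample and the experiment is deterministic", {
  ds <- tiny_dataset(60, seed = 14)
  clf <- midplane_classifier()
  cfg <- validation_config(m = 3, master_seed = 19)
  p1 <- downsample_experiment(ds, clf, proportions = c(0.5, 1.0),
                              draws_per_proportion = 3, cfg = cfg)
  p2 <- downsample_experiment(ds, clf, proportions = c(0.5, 1.0),
                              draws_per_proportion = 3, cfg = cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$realized_n <= 60))
})

test_that("proportions too small for the fold plan are skipped with a warning", {
  ds <- tiny_dataset(40, seed = 15)
  expect_warning(
    pts <- downsample_experiment(ds, midplane_classifier(),
                                 proportions = c(0.1, 1.0),
                                 draws_per_proportion = 1,
                                 cfg = validation_config(m = 2, K = 5,
                                                         master_seed = 1)),
    "skipping")
  expect_identical(unique(pts$proportion), 1.0)
  expect_error(downsample_experiment(ds, midplane_classifier(),
                                     proportions = c(0, 0.5)),
               class = "ecvalid_invalid_input")
})

test_that("trend fitting reproduces lines, preserves constants, and smooths noise", {
  x <- seq(0.2, 1, length.out = 20)
  pts <- data.frame(proportion = x, oa = 0.5 + 0.3 * x, aec = 0.9 - 0.2 * x)
  tr <- fit_trend(pts, span = 0.6)
  expect_lt(max(abs(tr$y_oa - (0.5 + 0.3 * tr$x))), 1e-6)
  expect_lt(max(abs(tr$y_aec - (0.9 - 0.2 * tr$x))), 1e-6)

  const <- data.frame(proportion = x, oa = rep(0.7, 20), aec = rep(0.4, 20))
  trc <- fit_trend(const)
  expect_true(all(abs(trc$y_oa - 0.7) < 1e-12))
  expect_true(all(abs(trc$y_aec - 0.4) < 1e-12))

  # smoothing reduces sup-error against a noiseless sigmoid
  set.seed(99)
  sig <- 1 / (1 + exp(-10 * (x - 0.6)))
  noisy <- pmin(1, pmax(0, sig + rnorm(20, sd = 0.08)))
  ptsn <- data.frame(proportion = x, oa = noisy, aec = noisy)
  trn <- fit_trend(ptsn, span = 0.6)
  expect_lt(max(abs(trn$y_oa - sig)), max(abs(noisy - sig)))

  expect_error(fit_trend(data.frame(proportion = 1:3 / 4, oa = 1:3 / 4,
                                    aec = 1:3 / 4)),
               class = "ecvalid_invalid_input")
  # undefined consistency points are excluded from the consistency fit only
  pts_na <- pts
  pts_na$aec[c(2, 5)] <- NA
  tr_na <- fit_trend(pts_na, span = 0.6)
  expect_length(tr_na$y_aec, length(tr_na$x))
  expect_lt(max(abs(stats::na.omit(tr_na$y_aec - (0.9 - 0.2 * tr_na$x)))), 1e-6)
})

test_that("rolling correlation handles monotone, noise and constant regimes", {
  # strictly monotone: every window correlation is exactly 1
  pairs <- data.frame(percent = seq(10, 100, length.out = 40),
                      value = seq(0.2, 0.9, length.out = 40))
  rc <- rolling_correlation(pairs, window_size = 8, n_boot = 50, seed = 2)
  expect_equal(nrow(rc), 40 - 8 + 1)
  expect_true(all(abs(rc$correlation - 1) < 1e-12))

  # metric independent of percentage: mean window correlation near 0 and
  # inside the pooled bootstrap interval, which covers 0
  set.seed(7)
  pairs_n <- data.frame(percent = seq_len(200), value = rnorm(200))
  rcn <- rolling_correlation(pairs_n, window_size = 50, n_boot = 300, seed = 3)
  m <- mean(rcn$correlation)
  expect_lt(abs(m), 0.2)
  expect_true(mean(rcn$ci_low) <= 0 && mean(rcn$ci_high) >= 0)
  expect_true(m >= mean(rcn$ci_low) && m <= mean(rcn$ci_high))

  # constant metric: undefined correlations, no crash
  rcc <- rolling_correlation(data.frame(percent = 1:20, value = rep(1, 20)),
                             window_size = 5, n_boot = 20, seed = 1)
  expect_true(all(is.na(rcc$correlation)))
  expect_true(all(is.na(rcc$ci_low)))

  expect_error(rolling_correlation(pairs, window_size = 2),
               class = "ecvalid_invalid_input")
  expect_error(rolling_correlation(pairs, window_size = 41),
               class = "ecvalid_invalid_input")
})

test_that("bootstrap intervals bracket the point estimate on seeded fixtures", {
  set.seed(31)
  pairs <- data.frame(percent = seq(1, 100, length.out = 120),
                      value = 0.5 + 0.004 * seq(1, 100, length.out = 120) +
                        rnorm(120, sd = 0.05))
  rc <- rolling_correlation(pairs, window_size = 30, n_boot = 400, seed = 4)
  ok <- !is.na(rc$correlation)
  inside <- rc$correlation[ok] >= rc$ci_low[ok] &
    rc$correlation[ok] <= rc$ci_high[ok]
  expect_gte(mean(inside), 0.99)
})
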