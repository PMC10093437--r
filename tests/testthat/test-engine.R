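test_that("internal approach: master error set unites disjoint fold sets and OA follows exactly", {
  ds <- tiny_dataset(100, seed = 6)
  planted <- as.integer(c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45))
  res <- run_internal(ds, planted_error_classifier(planted, ds),
                      validation_config(m = 20, master_seed = 11))
  for (r in seq_along(res$error_sets)) {
    s <- res$error_sets[[r]]
    expect_setequal(s$members, planted)        # folds partition ids: union recovers S
    expect_identical(s$support, sort(ds$ids))
    expect_identical(res$oa_per_repetition[r],
                     1 - length(s$members) / n_samples(ds))
  }
  expect_equal(res$mean_oa, 0.9)
  expect_equal(res$sd_oa, 0)
  expect_equal(res$ec_summary$aec, 1.0)
  expect_equal(res$ec_summary$sd, 0.0)
})

test_that("two runs with the same master seed are identical end to end", {
  ds <- tiny_dataset(60, seed = 7)
  cfg <- validation_config(m = 6, master_seed = 123)
  r1 <- run_internal(ds, random_error_classifier(0.15, ds), cfg)
  r2 <- run_internal(ds, random_error_classifier(0.15, ds), cfg)
  expect_identical(r1$oa_per_repetition, r2$oa_per_repetition)
  expect_identical(lapply(r1$error_sets, `[[`, "members"),
                   lapply(r2$error_sets, `[[`, "members"))
  expect_identical(r1$ec_summary$aec, r2$ec_summary$aec)
  r3 <- run_internal(ds, random_error_classifier(0.15, ds),
                     validation_config(m = 6, master_seed = 124))
  expect_false(identical(r1$oa_per_repetition, r3$oa_per_repetition))
})

test_that("a training-data-ignoring rule has consistency 1 under both approaches", {
  ds <- generate_boundary_dataset(synthetic_spec(120, seed = 8))
  res_i <- run_internal(ds, midplane_classifier(),
                        validation_config(m = 5, master_seed = 3))
  expect_equal(res_i$ec_summary$aec, 1.0)
  parts <- split_validation(ds, 0.25, seed = 2)
  res_e <- run_external(parts$train, parts$val, midplane_classifier(),
                        validation_config(m = 3, approach = "external",
                                          master_seed = 3))
  expect_equal(res_e$ec_summary$aec, 1.0)
})

test_that("external approach yields m*K error sets on the validation support", {
  ds <- tiny_dataset(110, seed = 9)
  parts <- split_validation(ds, 0.2, seed = 5)
  cfg <- validation_config(m = 2, K = 5, approach = "external", master_seed = 4)
  res <- run_external(parts$train, parts$val,
                      planted_error_classifier(parts$val$ids[1:4], ds), cfg)
  expect_length(res$error_sets, 10)                       # m*K
  expect_equal(res$pairwise$n_pairs_defined +
                 res$pairwise$n_pairs_undefined, 45)      # n(n-1)/2
  for (s in res$error_sets) {
    expect_identical(s$support, sort(parts$val$ids))
    expect_setequal(s$members, parts$val$ids[1:4])
  }
  expect_equal(res$ec_summary$aec, 1.0)
  expect_equal(res$ec_summary$sd, 0.0)
  # per-model validation accuracy consistent with the error sets
  expect_true(all(res$validation_accuracy == 1 - 4 / n_samples(parts$val)))
  # fold-test OA is reported separately and is perfect for this mock
  # (no planted id lies in the training set)
  expect_true(all(res$oa_per_repetition == 1))
})

test_that("external approach rejects degenerate inputs", {
  ds <- tiny_dataset(60, seed = 10)
  parts <- split_validation(ds, 0.2, seed = 1)
  cfg <- validation_config(m = 1, approach = "external", master_seed = 1)
  expect_error(run_external(parts$train, parts$train, midplane_classifier(), cfg),
               "overlap", class = "ecvalid_invalid_input")
  expect_error(run_external(parts$train,
                            ec_dataset(matrix(numeric(0), 0, 2,
                                              dimnames = list(NULL, colnames(ds$features))),
                                       factor(character(0), levels = c("a", "b"))[0],
                                       integer(0)),
                            midplane_classifier(), cfg),
               class = "ecvalid_invalid_input")
  expect_error(run_internal(ds, midplane_classifier(),
                            validation_config(m = 1, approach = "external")),
               class = "ecvalid_invalid_input")
})
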