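test_that("error consistency matches hand-enumerated cases", {
  expect_equal(error_consistency(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(error_consistency(c(1, 2), c(3, 4)), 0.0)
  expect_equal(error_consistency(c(1, 2), c(2, 3)), 1 / 3)
  expect_true(is.na(error_consistency(integer(0), integer(0))))
  expect_equal(error_consistency(integer(0), 7), 0.0)
})

test_that("error consistency is symmetric, bounded, and 1/0 exactly when it should be", {
  set.seed(11)
  for (i in 1:200) {
    a <- sample(0:49, sample(0:12, 1))
    b <- sample(0:49, sample(0:12, 1))
    v <- error_consistency(a, b)
    expect_identical(v, error_consistency(b, a))
    if (!is.na(v)) {
      expect_gte(v, 0); expect_lte(v, 1)
      expect_identical(v == 1, setequal(a, b) && length(a) > 0)
      expect_identical(v == 0,
                       length(intersect(a, b)) == 0 && length(union(a, b)) > 0)
    } else {
      expect_true(length(a) == 0 && length(b) == 0)
    }
  }
})

test_that("error set constructor enforces membership and support invariants", {
  es <- error_set(c(3, 1), repetition = 2, model_index = 1, support = 0:9)
  expect_identical(es$members, c(1L, 3L))
  expect_error(error_set(5, support = 0:4), class = "ecvalid_invalid_input")
  expect_error(error_set(integer(0), support = integer(0)),
               class = "ecvalid_invalid_input")
})

test_that("pairwise entries enumerate the upper triangle in lexicographic order", {
  sets <- list(c(1), c(1), c(2), integer(0))
  pec <- pairwise_ec(sets)
  expect_equal(nrow(pec$entries), 6)  # n(n-1)/2, n = 4
  expect_identical(pec$entries$i, c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(pec$entries$j, c(2L, 3L, 4L, 3L, 4L, 4L))
  expect_equal(pec$entries$ec, c(1, 0, 0, 0, 0, 0))
  # count conservation: stored + mirrored + diagonal = n^2
  expect_equal(2 * nrow(pec$entries) + pec$n_sets, pec$n_sets^2)
  expect_error(pairwise_ec(list(c(1))), class = "ecvalid_invalid_input")
})

test_that("pairwise values equal the brute-force oracle pair by pair", {
  set.seed(42)
  sets <- lapply(1:12, function(i) sample(0:30, sample(0:8, 1)))
  pec <- pairwise_ec(sets)
  for (r in seq_len(nrow(pec$entries))) {
    expected <- jaccard_oracle(sets[[pec$entries$i[r]]], sets[[pec$entries$j[r]]])
    if (is.na(expected)) expect_true(is.na(pec$entries$ec[r]))
    else expect_equal(pec$entries$ec[r], expected)
  }
})

test_that("streamed and materialized pairwise computations agree", {
  set.seed(5)
  sets <- lapply(1:30, function(i) sample(0:40, sample(0:10, 1)))
  full <- suppressWarnings(summarize_ec(pairwise_ec(sets, cap = 2000)))
  streamed <- suppressWarnings(summarize_ec(pairwise_ec(sets, cap = 10)))
  expect_null(pairwise_ec(sets, cap = 10)$entries)
  expect_equal(streamed$aec, full$aec)
  expect_equal(streamed$sd, full$sd)
  expect_identical(streamed$n_pairs_defined, full$n_pairs_defined)
  expect_identical(streamed$n_pairs_undefined, full$n_pairs_undefined)
})

test_that("summary uses sample SD over defined pairs and flags undefined ones", {
  pec <- pairwise_ec(list(c(1, 2), c(1, 2), integer(0)))
  # pairs: (1,2) = 1, (1,3) = 0, (2,3) = 0
  s <- summarize_ec(pec)
  expect_equal(s$aec, 1 / 3)
  expect_equal(s$sd, sd(c(1, 0, 0)))

  # hand-built values [1, 0.5, 0]: {1,2} vs {1,2}; {1,2} vs {2,3}... use sets
  pec2 <- pairwise_ec(list(c(1), c(1), c(2)))
  s2 <- summarize_ec(pec2)
  expect_equal(s2$aec, mean(c(1, 0, 0)))

  # undefined pairs excluded from the moments and warned about
  pec3 <- pairwise_ec(list(c(1, 2), integer(0), integer(0)))
  expect_warning(s3 <- summarize_ec(pec3), "undefined")
  expect_equal(s3$aec, 0)        # defined pairs: (1,2) = 0, (1,3) = 0
  expect_identical(s3$n_pairs_undefined, 1L)

  # all pairs defined and equal -> SD exactly 0
  s4 <- summarize_ec(pairwise_ec(list(c(7), c(7), c(7))))
  expect_equal(s4$aec, 1); expect_equal(s4$sd, 0)

  # no defined pairs -> undefined mean, counts intact
  expect_warning(s5 <- summarize_ec(pairwise_ec(list(integer(0), integer(0)))))
  expect_true(is.na(s5$aec))
  expect_identical(s5$n_pairs_defined, 0L)
  expect_identical(s5$n_pairs_undefined, 1L)
})

test_that("pairwise entries serialize to CSV and JSON with undefined as empty/null", {
  pec <- pairwise_ec(list(c(1, 2), integer(0), integer(0)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_ec(pec, csv, "csv")
  txt <- readLines(csv)
  expect_identical(txt[1], '"i","j","ec"')
  expect_identical(txt[4], "2,3,")      # both-empty pair -> empty field
  back <- read.csv(csv)
  expect_equal(back$ec, pec$entries$ec)

  js <- withr::local_tempfile(fileext = ".json")
  write_pairwise_ec(pec, js, "json")
  expect_match(paste(readLines(js), collapse = ""), '"ec":null')
})
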