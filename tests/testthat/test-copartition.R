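test_that("pearson_r handles exact and oracle-checked cases", {
  expect_equal(pearson_r(c(1, 2, 5, 3), c(1, 2, 5, 3)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(3:50, 1))
    y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), tolerance = 1e-12)
})

test_that("pearson_r rejects degenerate inputs", {
  expect_error(pearson_r(1:2, 2:1), "sample-size")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_r(1:3, c(2, 2, 2)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(c(1, NA, 3), 1:3), "missing")
})

test_that("leave-one-out deltas match a brute-force cor() oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:25, 1)
    x <- rnorm(n); y <- rnorm(n)
    pp <- pair_profile(x, y)
    d <- loo_correlation_deltas(pp)
    bf <- oracle_loo(x, y)
    expect_equal(d$r_loo, bf, tolerance = 1e-12)
    expect_equal(d$delta, bf - cor(x, y), tolerance = 1e-12)
    expect_equal(sum(d$r_loo), sum(bf), tolerance = 1e-10)
  }
})

test_that("collinear pairs give zero deltas; outliers the maximal delta", {
  pp <- pair_profile(c(1, 2, 3, 4, 5), 2 * c(1, 2, 3, 4, 5) + 1)
  d <- loo_correlation_deltas(pp)
  expect_equal(d$delta, rep(0, 5))

  # 3 points on a line plus one gross outlier: its removal is uniquely best
  x <- c(1, 2, 3, 10)
  y <- c(1, 2, 3, -20)
  d2 <- loo_correlation_deltas(pair_profile(x, y))
  expect_identical(which.max(d2$delta), 4L)
  expect_equal(d2$r_loo[4], 1.0)
  expect_equal(d2$r_loo, oracle_loo(x, y), tolerance = 1e-12)
})

test_that("removals leaving a constant vector get -Inf and are never picked", {
  x <- c(1, 1, 1, 5)
  y <- c(0, 2, 4, 6)
  d <- loo_correlation_deltas(pair_profile(x, y))
  expect_identical(d$delta[4], -Inf)  # dropping S4 leaves x constant
  expect_true(all(is.finite(d$delta[1:3])))
})

test_that("perfectly correlated pairs are never split", {
  pp <- pair_profile(1:10, 0.5 * (1:10) + 3)
  res <- greedy_partition(pp)
  expect_length(res$cohort2, 0)
  expect_identical(nrow(res$trace), 0L)
  expect_equal(res$r_initial, 1.0)
  expect_equal(res$r_final, 1.0)
})

test_that("off-line points are pruned until the on-line core remains", {
  # 8 points exactly on a positive line plus 2 off-line points
  x <- c(1:8, 4, 6)
  y <- c(2 * (1:8) + 1, 30, -25)
  ids <- c(paste0("L", 1:8), "OFF1", "OFF2")
  res <- greedy_partition(pair_profile(x, y, sample_ids = ids))
  expect_setequal(res$cohort2, c("OFF1", "OFF2"))
  expect_setequal(res$cohort1, paste0("L", 1:8))
  expect_equal(res$r_final, 1.0)
  orc <- oracle_greedy(x, y)
  expect_identical(sort(orc$kept), 1:8)
})

test_that("greedy removal sequence equals an independent brute-force loop", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(c(9, 12, 20, 30), 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    res <- greedy_partition(pair_profile(x, y))
    orc <- oracle_greedy(x, y)
    expect_identical(res$cohort2, paste0("S", orc$removed))
    expect_setequal(res$cohort1, paste0("S", orc$kept))
  }
})

test_that("trace increases strictly and the exit is locally optimal", {
  set.seed(37)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    pp <- pair_profile(rnorm(n), rnorm(n))
    res <- greedy_partition(pp)
    if (nrow(res$trace) > 0) {
      expect_true(all(res$trace$r_after > res$trace$r_before))
      expect_true(all(diff(res$trace$r_after) > 0))
      expect_equal(res$trace$r_after[nrow(res$trace)], res$r_final)
    }
    expect_gte(res$r_final, res$r_initial)
    expect_lte(nrow(res$trace), n - res$min_cohort)
    expect_setequal(c(res$cohort1, res$cohort2), paste0("S", 1:n))
    # local optimality: no remaining single removal increases r
    if (length(res$cohort1) >= 4) {
      d <- loo_correlation_deltas(pp, members = res$cohort1)
      expect_lte(max(d$delta), 1e-12)
    }
  }
})

test_that("partition is deterministic and tie rules are honoured", {
  set.seed(41)
  pp <- pair_profile(rnorm(15), rnorm(15))
  expect_identical(greedy_partition(pp), greedy_partition(pp))

  # exact tie by symmetry: two mirrored off-line points
  x <- c(1, 2, 3, 4, 5, 3, 3)
  y <- c(1, 2, 3, 4, 5, 3 + 10, 3 - 10)
  ids <- c(paste0("L", 1:5), "HI", "LO")
  lo_first <- greedy_partition(pair_profile(x, y, sample_ids = ids),
                               tie_rule = "lowest-index")
  hi_first <- greedy_partition(pair_profile(x, y, sample_ids = ids),
                               tie_rule = "highest-index")
  expect_identical(lo_first$trace$sample_id[1], "HI")
  expect_identical(hi_first$trace$sample_id[1], "LO")
  expect_setequal(lo_first$cohort2, c("HI", "LO"))
})

test_that("partition input contracts are enforced", {
  expect_error(greedy_partition(pair_profile(1:3, c(2, 1, 3)), min_cohort = 2),
               "min_cohort")
  expect_error(greedy_partition(pair_profile(1:3, c(2, 1, 3)), min_cohort = 4),
               "sample-size")
  expect_error(greedy_partition(pair_profile(c(1, 1, 1, 1), 1:4)), "constant")
})

test_that("partition report serializes cohorts and removal steps", {
  x <- c(1:8, 4, 6)
  y <- c(2 * (1:8) + 1, 30, -25)
  res <- greedy_partition(pair_profile(x, y))
  f <- withr::local_tempfile()
  summary <- write_partition_report(res, f)
  rep_df <- read.delim(f)
  expect_identical(nrow(rep_df), 10L)
  expect_identical(sum(rep_df$cohort == 2), 2L)
  expect_true(all(is.na(rep_df$removal_step[rep_df$cohort == 1])))
  expect_equal(summary$r_final, 1.0)
  expect_identical(summary$n1, 8L)
  expect_match(summary$note, "selection-biased")
})
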