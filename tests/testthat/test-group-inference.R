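resp_fixture <- function(values, metric = "brs", subject = "s",
                         condition = "normoxia") {
  n <- length(values)
  data.frame(subject = rep(subject, n), condition = rep(condition, n),
             bolus_index = seq_len(n),
             delta_sbp = if (metric == "delta_sbp") values else rep(20, n),
             brs_slope = if (metric == "brs") values else rep(15, n),
             accepted = rep(TRUE, n), stringsAsFactors = FALSE)
}

test_that("the per-subject median shrugs off outlier boli", {
  st <- condition_statistic(resp_fixture(c(1, 2, 100)), "brs", "median")
  expect_equal(st$value, 2)
  expect_equal(st$n, 3)
  # single value: median = mean = x, zero-width dispersion
  one <- condition_statistic(resp_fixture(7), "brs", "median")
  expect_equal(one$value, 7)
  expect_equal(one$sem, 0)
  # symmetric values: median equals mean
  sym <- c(10, 12, 14, 16, 18)
  expect_equal(condition_statistic(resp_fixture(sym), "brs", "median")$value,
               condition_statistic(resp_fixture(sym), "brs", "mean")$value)
  # contaminating one bolus moves the median by at most the order-statistic
  # gap, while the mean shifts by 50/n
  base <- c(10, 11, 12, 13, 14)
  cont <- c(10, 11, 62, 13, 14)
  expect_equal(condition_statistic(resp_fixture(cont), "brs", "median")$value -
                 condition_statistic(resp_fixture(base), "brs", "median")$value,
               1)  # 12 -> 13, bounded by the gap to the next order statistic
  expect_equal(condition_statistic(resp_fixture(cont), "brs", "mean")$value -
                 condition_statistic(resp_fixture(base), "brs", "mean")$value,
               10)
  expect_error(condition_statistic(resp_fixture(numeric(0)), "brs"),
               "no accepted boli")
})

test_that("paired test: identical vectors give t = 0, constant shift is exact", {
  x <- c(10, 14, 18, 22)
  same <- paired_group_test(x, x)
  expect_equal(same$paired_t, 0)
  expect_equal(same$p, 1)
  shift <- paired_group_test(x, x + 3)
  expect_equal(shift$mean_difference, 3)
  expect_equal(shift$sem_difference, 0)
  expect_true(shift$degenerate)
  expect_error(paired_group_test(x, x[1:2]), "misaligned")
})

test_that("paired test matches t.test and the published group aggregate", {
  brs <- reference_summaries("brs")
  g <- paired_group_test(brs$brs_normoxia_mean, brs$brs_hypoxia_mean,
                         subjects = brs$subject, metric = "brs")
  expect_equal(g$group_mean_normoxia, 19.9, tolerance = 0.05 / 19.9)
  expect_lt(g$p, 0.001)
  expect_lt(g$mean_difference, 0)      # BRS falls in hypoxia
  tt <- t.test(brs$brs_hypoxia_mean, brs$brs_normoxia_mean, paired = TRUE)
  expect_equal(g$paired_t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(g$p, tt$p.value, tolerance = 1e-9)
  expect_equal(g$df, 8)
})

test_that("change correlation: exact collinearity, null case, degenerate case", {
  d <- c(-1, 2, 5, -3)
  expect_equal(correlate_changes(d, 2 * d)$r, 1, tolerance = 1e-12)
  flat <- correlate_changes(rep(1, 4), d)
  expect_true(flat$undefined)
  expect_true(is.na(flat$r))
  # per-subject changes of the two published metrics are uncorrelated
  brs <- reference_summaries("brs")
  prs <- reference_summaries("pressor")
  cc <- correlate_changes(brs$brs_hypoxia_mean - brs$brs_normoxia_mean,
                          prs$dsbp_hypoxia_mean - prs$dsbp_normoxia_mean)
  expect_lt(abs(cc$r), 0.5)
  expect_gt(cc$p, 0.05)
})

test_that("group aggregation recovers the generator's condition means", {
  spec <- small_cohort_spec(n_boli = 10)
  truth_norm <- mean(c(20, 18, 25))
  ok <- vapply(1:20, function(seed) {
    resp <- extract_cohort(simulate_cohort(spec, seed = seed))
    g <- group_analysis(resp, "brs", statistic = "mean")
    abs(g$group_mean_normoxia - truth_norm) <= 2 * g$group_sem_normoxia
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
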