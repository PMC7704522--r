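test_that("summary-based Welch test equals the raw-value Welch test", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- rnorm(sample(5:25, 1), 15, 4)
      y <- rnorm(sample(5:25, 1), 11, 6)
      w <- welch_t_from_summary(mean(x), sd(x) / sqrt(length(x)), length(x),
                                mean(y), sd(y) / sqrt(length(y)), length(y))
      tt <- t.test(x, y)
      expect_equal(w$t, unname(tt$statistic), tolerance = 1e-9)
      expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
      expect_equal(w$p, tt$p.value, tolerance = 1e-9)
    }
  })
})

test_that("pooled variant equals the classical equal-variance test", {
  withr::with_seed(6, {
    x <- rnorm(12, 20, 5); y <- rnorm(18, 15, 5)
    w <- welch_t_from_summary(mean(x), sd(x) / sqrt(12), 12,
                              mean(y), sd(y) / sqrt(18), 18, pooled = TRUE)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(w$p, tt$p.value, tolerance = 1e-9)
  })
})

test_that("the summary test is antisymmetric and handles degenerate input", {
  a <- welch_t_from_summary(14, 1.2, 10, 10, 0.7, 12)
  b <- welch_t_from_summary(10, 0.7, 12, 14, 1.2, 10)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 1, 10)$p, 1)
  expect_equal(welch_t_from_summary(5, 0, 10, 5, 0, 10)$t, 0)
  deg <- welch_t_from_summary(6, 0, 10, 5, 0, 10)
  expect_true(is.infinite(deg$t) && deg$t > 0)
  expect_equal(deg$p, 0)
})

test_that("individual comparison classifies by sign and significance", {
  ms <- function(values, cc) structure(
    list(subject = "s", condition = cc, metric = "brs", values = values,
         n = length(values), mean = mean(values),
         sem = sd(values) / sqrt(length(values))),
    class = "metric_sample")
  withr::with_seed(8, {
    norm <- rnorm(20, 20, 3)
    hyp <- rnorm(20, 12, 3)
    cmp <- compare_individual(ms(norm, "normoxia"), ms(hyp, "hypoxia"))
    expect_equal(cmp$classification, "decreased")
    expect_lt(cmp$difference, 0)
    expect_lt(cmp$ci95_high, 0)
    # CI must bracket the observed difference
    expect_lt(cmp$ci95_low, cmp$difference)
  })
  # noise-free distinct constants: infinite t, classification by sign
  cmp2 <- compare_individual(ms(rep(10, 5), "normoxia"),
                             ms(rep(12, 5), "hypoxia"))
  expect_true(is.infinite(cmp2$t_statistic))
  expect_equal(cmp2$classification, "increased")
  expect_error(compare_individual(ms(1:5, "normoxia"), ms(3, "hypoxia")),
               "at least 2")
})

test_that("detection rate rises with effect size and repetitions", {
  sens <- function(delta, n) {
    withr::with_seed(1000 + round(delta * 10) + n, {
      p <- baroN1:::welch_p_cols(
        matrix(rnorm(n * 400, delta, 6), n),
        matrix(rnorm(n * 400, 0, 6), n))
      mean(p < 0.05)
    })
  }
  by_delta <- c(sens(2, 10), sens(6, 10), sens(12, 10))
  by_n <- c(sens(6, 5), sens(6, 10), sens(6, 20))
  expect_true(all(diff(by_delta) > 0))
  expect_true(all(diff(by_n) > 0))
})

test_that("cohort classification tallies and rejects duplicate subjects", {
  cmp <- compare_from_summary(reference_summaries("brs"), "brs")
  counts <- classify_cohort(cmp)
  expect_named(counts, c("decreased", "increased", "unchanged"))
  expect_equal(sum(counts), 9)
  expect_error(classify_cohort(rbind(cmp, cmp[1, ])), "duplicate")
})

test_that("Holm correction is available but off by default", {
  resp <- extract_cohort(simulate_cohort(small_cohort_spec(n_boli = 6),
                                         seed = 3))
  plain <- compare_cohort(resp, "brs")
  holm <- compare_cohort(resp, "brs", p_adjust = "holm")
  expect_true(all(holm$p_value >= plain$p_value))
})
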