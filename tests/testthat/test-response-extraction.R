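test_that("baseline SBP averages the ten beats immediately before the bolus", {
  sbp <- c(rep(110, 10), 121:130, 140, 141, 142, 143)
  beats <- manual_beats(sbp)
  # bolus falls between beat 20 (t = 19) and beat 21 (t = 20)
  expect_equal(baseline_sbp(beats, 19.5), mean(121:130))
  expect_equal(baseline_sbp(beats, 19.5), 125.5)
  expect_equal(baseline_sbp(manual_beats(rep(120, 25)), 19.5), 120)
  expect_error(baseline_sbp(beats, 5), "pre-bolus beats")
})

test_that("peak SBP is the best three-beat window, earliest on ties", {
  sbp <- c(rep(120, 12), 130, 131, 135, 140, 139, 132, rep(120, 3))
  beats <- manual_beats(sbp)
  pk <- peak_sbp(beats, 11.5)
  expect_equal(pk$sbp_peak, mean(c(135, 140, 139)))
  expect_equal(pk$peak_time_s, beats$time_s[16])  # beat carrying the 140
  # monotone rise to a plateau: the plateau value itself
  sbp2 <- c(rep(120, 12), 130, 140, 150, 150, 150, 150)
  expect_equal(peak_sbp(manual_beats(sbp2), 11.5)$sbp_peak, 150)
  expect_error(peak_sbp(manual_beats(rep(120, 13)), 11.5),
               "fewer than 3 beats")
})

test_that("peak search matches brute-force enumeration of all 3-beat windows", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      sbp <- 120 + round(rnorm(40, 0, 8), 1)
      beats <- manual_beats(clamp_num(sbp, 60, 290))
      bolus_t <- 14.5
      pk <- peak_sbp(beats, bolus_t)
      idx <- which(beats$time_s > bolus_t & beats$time_s <= bolus_t + 60)
      best <- -Inf
      for (i in idx[seq_len(length(idx) - 2)])
        best <- max(best, mean(beats$sbp_mmhg[i:(i + 2)]))
      expect_equal(pk$sbp_peak, best)
    }
  })
})

test_that("an exact linear reflex gives the exact slope, intercept and r", {
  beats <- linear_reflex_beats(slope = 20, intercept = -1600)
  est <- estimate_brs(beats, 11.5)
  expect_equal(est$slope, 20, tolerance = 1e-12)
  expect_equal(est$intercept, -1600, tolerance = 1e-9)
  expect_equal(est$r, 1, tolerance = 1e-12)
  expect_gte(est$n, 5)
})

test_that("regression agrees with lm on the same pairs to 1e-9", {
  p <- condition_params(brs_true = 14, brs_between_sd = 3)
  sim <- simulate_beats(p, bolus_schedule(n_boli = 4), seed = 21)
  for (k in 1:4) {
    est <- estimate_brs(sim$beats, sim$events$time_s[k])
    x <- sim$beats$sbp_mmhg[est$pairs]
    y <- sim$beats$rri_ms[est$pairs + 1L]
    fit <- lm(y ~ x)
    expect_equal(est$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(est$intercept, unname(coef(fit)[1]), tolerance = 1e-9)
    expect_equal(est$r, cor(x, y), tolerance = 1e-12)
  }
})

test_that("shifting all RR intervals changes the intercept only", {
  beats <- linear_reflex_beats()
  shifted <- beats
  shifted$rri_ms <- beats$rri_ms + 150
  a <- estimate_brs(beats, 11.5)
  b <- estimate_brs(shifted, 11.5)
  expect_equal(b$slope, a$slope, tolerance = 1e-12)
  expect_equal(b$r, a$r, tolerance = 1e-12)
  expect_equal(b$intercept, a$intercept + 150, tolerance = 1e-9)
})

test_that("scaling SBP deviations by c scales the slope by 1/c", {
  beats <- linear_reflex_beats()
  a <- estimate_brs(beats, 11.5)
  scaled <- beats
  scaled$sbp_mmhg <- 120 + 2 * (beats$sbp_mmhg - 120)
  b <- estimate_brs(scaled, 11.5)
  expect_equal(b$slope, a$slope / 2, tolerance = 1e-9)
})

test_that("a rising pressure with pure-noise RR intervals is usually rejected", {
  withr::with_seed(31, {
    accepted <- vapply(1:200, function(i) {
      sbp <- c(rep(120, 12), 120 + seq(2, 30, length.out = 15))
      rri <- c(rep(900, 12), 900 + rnorm(15, 0, 30))
      beats <- manual_beats(sbp, clamp_num(rri, 300, 2000))
      est <- estimate_brs(beats, 11.5)
      !is.na(est$r) && est$r > 0.5
    }, logical(1))
    expect_lte(mean(accepted), 0.15)
  })
})

test_that("the acceptance rule is strict: r = 0.5 is rejected", {
  expect_false(baroN1:::slope_accepted(0.5))
  expect_true(baroN1:::slope_accepted(0.5 + 1e-12))
  expect_false(baroN1:::slope_accepted(NA_real_))
})

test_that("rejected boli are carried, never dropped, and delta-SBP is exact", {
  p <- condition_params(brs_true = 2, brs_between_sd = 2, rri_noise_sd = 40)
  sim <- simulate_beats(p, bolus_schedule(n_boli = 6), seed = 4)
  r <- extract_condition(sim$beats, sim$events)
  expect_equal(nrow(r), 6)
  expect_true(any(!r$accepted))                 # weak reflex: some rejections
  expect_true(all(!r$accepted[!is.na(r$reject_reason)]))
  expect_equal(r$delta_sbp, r$sbp_peak - r$sbp_baseline, tolerance = 1e-12)
  expect_true(all(!is.na(r$delta_sbp)))         # pressor metric keeps all boli
})

test_that("condition extraction guards window overlap and empty schedules", {
  sim <- simulate_beats(condition_params(), bolus_schedule(n_boli = 3),
                        seed = 2)
  expect_equal(nrow(extract_condition(sim$beats, sim$events)), 3)
  expect_equal(nrow(extract_condition(sim$beats, sim$events[0, ])), 0)
  close_events <- data.frame(bolus_index = 1:2,
                             time_s = c(130, 200),  # 70 s apart
                             dose_ug = 50, condition = "normoxia")
  expect_error(extract_condition(sim$beats, close_events), "overlap")
})
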