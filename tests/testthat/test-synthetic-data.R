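test_that("constructors reject unphysiological parameters", {
  expect_error(condition_params(brs_true = -1), "brs_true")
  expect_error(condition_params(spo2 = 0), "spo2")
  expect_error(condition_params(hr_baseline = 20), "300-2000")
  expect_error(bolus_schedule(n_boli = 0), "n_boli")
  expect_error(bolus_schedule(interval_s = 60), "exceed 60")
})

test_that("simulation is bit-reproducible for identical spec and seed", {
  p <- condition_params()
  s <- bolus_schedule(n_boli = 3)
  expect_identical(simulate_beats(p, s, seed = 42),
                   simulate_beats(p, s, seed = 42))
  spec <- small_cohort_spec()
  expect_identical(simulate_cohort(spec, seed = 7),
                   simulate_cohort(spec, seed = 7))
})

test_that("beat times advance by exactly the RR interval", {
  sim <- simulate_beats(condition_params(), bolus_schedule(n_boli = 2),
                        seed = 3)
  b <- sim$beats
  expect_equal(diff(b$time_s) * 1000, b$rri_ms[-1], tolerance = 1e-9)
})

test_that("noise-free coupling is recovered exactly by the estimator", {
  p <- condition_params(brs_true = 20, rri_noise_sd = 0, sbp_noise_sd = 0)
  sim <- simulate_beats(p, bolus_schedule(n_boli = 3), seed = 1)
  r <- extract_condition(sim$beats, sim$events)
  expect_equal(r$brs_slope, rep(20, 3), tolerance = 1e-9)
  expect_equal(r$pearson_r, rep(1, 3), tolerance = 1e-9)
  expect_true(all(r$accepted))
  # the per-bolus peak amplitude is recovered up to beat discretization
  expect_equal(r$delta_sbp, rep(22, 3), tolerance = 0.01)
})

test_that("zero baroreflex gain leaves the RR interval flat through the rise", {
  p <- condition_params(brs_true = 0, rri_noise_sd = 0, sbp_noise_sd = 0)
  sim <- simulate_beats(p, bolus_schedule(n_boli = 2), seed = 1)
  expect_equal(diff(range(sim$beats$rri_ms)), 0)
  expect_gt(diff(range(sim$beats$sbp_mmhg)), 15)  # the pressor rise is there
})

test_that("a schedule extending beyond the recording names the offending bolus", {
  expect_error(
    simulate_beats(condition_params(), bolus_schedule(n_boli = 5),
                   duration_s = 500, seed = 1),
    "bolus 3")  # boli at 120, 360, 600, ... s: the third is the first to overrun
})

test_that("extracted pressor response tracks the generator truth across seeds", {
  p <- condition_params(sbp_baseline = 133, hr_baseline = 63,
                        brs_true = 19.9, dsbp_true = 22,
                        brs_between_sd = 4, dsbp_between_sd = 6)
  s <- bolus_schedule(n_boli = 20)
  devs <- vapply(1:50, function(seed) {
    sim <- simulate_beats(p, s, seed = seed)
    mean(extract_condition(sim$beats, sim$events)$delta_sbp) - 22
  }, numeric(1))
  # per-condition mean of 20 boli should sit within 2 SEM of truth
  # (SEM = 6 / sqrt(20)); the 3-beat max-window statistic gives a small
  # positive bias that this band accommodates
  expect_lt(abs(mean(devs)), 2 * 6 / sqrt(20))
})

test_that("per-bolus regression quality degrades monotonically with RRI noise", {
  s <- bolus_schedule(n_boli = 5)
  mean_r <- vapply(c(5, 25, 80), function(noise) {
    rs <- lapply(1:6, function(seed) {
      p <- condition_params(brs_true = 15, rri_noise_sd = noise)
      sim <- simulate_beats(p, s, seed = seed)
      extract_condition(sim$beats, sim$events)$pearson_r
    })
    mean(unlist(rs), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})

test_that("cohort simulation has the protocol structure and guards ids", {
  spec <- small_cohort_spec()
  recs <- simulate_cohort(spec, seed = 2)
  expect_length(recs, 3)
  for (rec in recs) {
    expect_setequal(names(rec$beats), c("normoxia", "hypoxia"))
    expect_setequal(rec$condition_order, c("normoxia", "hypoxia"))
    for (cc in names(rec$events)) {
      expect_equal(nrow(rec$events[[cc]]), 4)
      expect_true(all(rec$events[[cc]]$time_s >=
                        min(rec$beats[[cc]]$time_s)))
      expect_true(all(rec$events[[cc]]$time_s <=
                        max(rec$beats[[cc]]$time_s)))
    }
  }
  expect_error(simulate_cohort(c(spec, spec[1]), seed = 2), "duplicate")
})

test_that("subjects have independent substreams: order does not matter", {
  spec <- small_cohort_spec()
  a <- simulate_cohort(spec, seed = 5)
  b <- simulate_cohort(rev(spec), seed = 5)
  expect_identical(a[["s2"]], b[["s2"]])
})

test_that("an individual with identical conditions is classified unchanged", {
  p_norm <- condition_params("normoxia", brs_true = 15, brs_between_sd = 5,
                             dsbp_between_sd = 6)
  p_hyp <- condition_params("hypoxia", brs_true = 15, brs_between_sd = 5,
                            dsbp_between_sd = 6)
  sched <- bolus_schedule(n_boli = 20)
  spec <- list(subject_spec("null", p_norm, p_hyp, sched))
  unchanged <- vapply(1:40, function(seed) {
    resp <- extract_cohort(simulate_cohort(spec, seed = seed))
    compare_cohort(resp, "brs")$classification == "unchanged"
  }, logical(1))
  # bounded by the type-I error of the alpha = 0.05 test
  expect_gte(mean(unchanged), 0.9)
})

test_that("a cohort-wide true BRS drop yields a positive paired difference", {
  sched <- bolus_schedule(n_boli = 20)
  spec <- lapply(1:4, function(i) subject_spec(
    paste0("s", i),
    condition_params("normoxia", brs_true = 19.9, brs_between_sd = 6.5,
                     dsbp_between_sd = 6),
    condition_params("hypoxia", sbp_baseline = 135, hr_baseline = 76,
                     brs_true = 14.1, brs_between_sd = 6.5,
                     dsbp_between_sd = 6, spo2 = 81),
    sched))
  drops <- vapply(1:25, function(seed) {
    resp <- extract_cohort(simulate_cohort(spec, seed = seed))
    g <- group_analysis(resp, "brs")
    -g$mean_difference   # hypoxia - normoxia should be negative
  }, numeric(1))
  expect_true(all(drops > 0))
})
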