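# Fixtures are built in code: hand-laid beat tables with known geometry, and
# small simulated recordings.

clamp_num <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Beat series with one beat per second and fully specified SBP values;
# RR intervals default to a constant 1000 ms (valid, though not required to
# match the 1 s spacing for these geometric fixtures).
manual_beats <- function(sbp, rri = rep(1000, length(sbp)),
                         dt = rep(1, length(sbp))) {
  beat_series(data.frame(beat_index = seq_along(sbp),
                         time_s = cumsum(dt) - dt[1],
                         rri_ms = rri, sbp_mmhg = sbp),
              subject_id = "fix", condition = "normoxia")
}

one_bolus_event <- function(time_s, index = 1L) {
  data.frame(bolus_index = index, time_s = time_s, dose_ug = 50,
             condition = "normoxia")
}

# A beat series whose post-bolus rise follows an exact linear reflex:
# RRI_(i+1) = intercept + slope * SBP_i. Pre-bolus beats sit at a constant
# baseline so the rise-phase onset is the first post-bolus beat.
linear_reflex_beats <- function(slope = 20, intercept = -1600,
                                baseline = 120, rise = 1:15,
                                n_pre = 12) {
  sbp <- c(rep(baseline, n_pre), baseline + rise, rep(baseline + max(rise), 3))
  rri <- c(1000, intercept + slope * sbp[-length(sbp)])
  rri <- pmin(pmax(rri, 300), 2000)
  manual_beats(sbp, rri)
}

small_cohort_spec <- function(n_boli = 4) {
  sched <- bolus_schedule(n_boli = n_boli, interval_s = 240)
  list(
    subject_spec("s1",
                 condition_params("normoxia", brs_true = 20,
                                  brs_between_sd = 4, dsbp_between_sd = 6),
                 condition_params("hypoxia", sbp_baseline = 135,
                                  hr_baseline = 76, brs_true = 10,
                                  brs_between_sd = 4, dsbp_between_sd = 6,
                                  spo2 = 81),
                 sched),
    subject_spec("s2",
                 condition_params("normoxia", brs_true = 18,
                                  brs_between_sd = 4, dsbp_between_sd = 6),
                 condition_params("hypoxia", sbp_baseline = 135,
                                  hr_baseline = 76, brs_true = 17,
                                  brs_between_sd = 4, dsbp_between_sd = 6,
                                  spo2 = 81),
                 sched),
    subject_spec("s3",
                 condition_params("normoxia", brs_true = 25,
                                  brs_between_sd = 4, dsbp_between_sd = 6),
                 condition_params("hypoxia", sbp_baseline = 135,
                                  hr_baseline = 76, brs_true = 19,
                                  brs_between_sd = 4, dsbp_between_sd = 6,
                                  spo2 = 81),
                 sched))
}
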