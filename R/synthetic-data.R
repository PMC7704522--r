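#' Condition parameters for the beat-to-beat simulator
#'
#' Bundles the physiological state of one subject under one experimental
#' condition. Heart period and systolic pressure define the operating point;
#' \code{brs_true} couples the RR interval of the next beat to the current
#' systolic pressure deviation; \code{dsbp_true} is the mean pressor response
#' to the standard phenylephrine bolus. Two bolus-to-bolus dispersion terms
#' (\code{brs_between_sd}, \code{dsbp_between_sd}) reproduce the empirical
#' per-bolus spread of slope and pressor amplitude, on top of white beat-level
#' noise (\code{rri_noise_sd}, \code{sbp_noise_sd}).
#'
#' Respiratory fields (\code{spo2}, \code{ve}, \code{vt}, \code{rr_breaths},
#' \code{etco2}) are carried as condition metadata for the chemoreflex module;
#' breathing itself is not simulated beat by beat.
#'
#' @param label condition name, \code{"normoxia"} or \code{"hypoxia"}.
#' @param sbp_baseline baseline systolic blood pressure, mmHg.
#' @param hr_baseline baseline heart rate, beats/min.
#' @param brs_true cardiovagal baroreflex slope, ms/mmHg (>= 0).
#' @param dsbp_true mean systolic rise per standard bolus, mmHg.
#' @param rri_noise_sd white beat-level RR-interval noise SD, ms.
#' @param sbp_noise_sd white beat-level systolic pressure noise SD, mmHg.
#' @param brs_between_sd SD of the per-bolus true slope around
#'   \code{brs_true}, ms/mmHg.
#' @param dsbp_between_sd SD of the per-bolus pressor amplitude around
#'   \code{dsbp_true}, mmHg (draws truncated below at 5 mmHg).
#' @param spo2 arterial oxygen saturation, percent.
#' @param ve minute ventilation, l/min.
#' @param vt tidal volume, l.
#' @param rr_breaths respiratory rate, breaths/min.
#' @param etco2 end-tidal CO2, mmHg.
#' @param rsa_amplitude optional respiratory sinus arrhythmia amplitude, ms.
#'   Off (0) by default; when positive a sinusoid at \code{rr_breaths} is
#'   added to the RR interval so that ventilatory entrainment of the
#'   estimator can be probed.
#' @return An object of class \code{condition_params}.
#' @export
condition_params <- function(label = c("normoxia", "hypoxia"),
                             sbp_baseline = 133, hr_baseline = 63,
                             brs_true = 19.9, dsbp_true = 22,
                             rri_noise_sd = 25, sbp_noise_sd = 3,
                             brs_between_sd = 0, dsbp_between_sd = 0,
                             spo2 = 98.1, ve = 11.86, vt = 0.77,
                             rr_breaths = 16, etco2 = 38.31,
                             rsa_amplitude = 0) {
  label <- match.arg(label)
  p <- list(label = label, sbp_baseline = sbp_baseline,
            hr_baseline = hr_baseline, brs_true = brs_true,
            dsbp_true = dsbp_true, rri_noise_sd = rri_noise_sd,
            sbp_noise_sd = sbp_noise_sd, brs_between_sd = brs_between_sd,
            dsbp_between_sd = dsbp_between_sd, spo2 = spo2, ve = ve, vt = vt,
            rr_breaths = rr_breaths, etco2 = etco2,
            rsa_amplitude = rsa_amplitude)
  validate_condition_params(p)
  structure(p, class = "condition_params")
}

validate_condition_params <- function(p) {
  if (p$brs_true < 0) stop_("brs_true must be >= 0 (got %g)", p$brs_true)
  if (p$sbp_baseline <= 0) stop_("sbp_baseline must be positive")
  if (p$hr_baseline <= 0) stop_("hr_baseline must be positive")
  if (p$spo2 <= 0 || p$spo2 > 100) stop_("spo2 must lie in (0, 100]")
  rri0 <- 60000 / p$hr_baseline
  if (rri0 < 300 || rri0 > 2000)
    stop_("hr_baseline %g implies RR interval %.0f ms outside 300-2000 ms",
          p$hr_baseline, rri0)
  for (f in c("rri_noise_sd", "sbp_noise_sd", "brs_between_sd",
              "dsbp_between_sd", "rsa_amplitude"))
    if (p[[f]] < 0) stop_("%s must be >= 0", f)
  invisible(p)
}

#' Bolus schedule
#'
#' Timing of the repeated phenylephrine administrations within one condition.
#' The default reproduces the standard protocol: 20 boli, one every 4 min,
#' with the first bolus 2 min after the start of the analyzed segment.
#'
#' @param n_boli number of boli (>= 1).
#' @param interval_s seconds between boli; must exceed 60 s so that the peak
#'   search window of one bolus cannot reach the baseline window of the next.
#' @param dose_ug dose per bolus, micrograms (metadata only; the simulator
#'   uses the condition's \code{dsbp_true} for the response amplitude).
#' @param first_bolus_s time of the first bolus, seconds from segment start;
#'   must leave room for at least 10 pre-bolus baseline beats.
#' @return An object of class \code{bolus_schedule}.
#' @export
bolus_schedule <- function(n_boli = 20, interval_s = 240, dose_ug = 50,
                           first_bolus_s = 120) {
  if (!is_count(n_boli) || n_boli < 1) stop_("n_boli must be a count >= 1")
  if (interval_s <= 60) stop_("interval_s must exceed 60 s (got %g)", interval_s)
  if (first_bolus_s <= 0) stop_("first_bolus_s must be positive")
  structure(list(n_boli = as.integer(n_boli), interval_s = interval_s,
                 dose_ug = dose_ug, first_bolus_s = first_bolus_s),
            class = "bolus_schedule")
}

#' Shape of the simulated pressor transient
#'
#' The systolic response to one bolus is a smooth unimodal gamma-like kernel
#' \code{(t/tp)^shape * exp(shape * (1 - t/tp))}, rising to its peak amplitude
#' at \code{peak_time_s} and decayed to < 0.1 percent of peak by
#' \code{support_s}, where it is truncated to exactly zero. Downstream
#' extraction must not (and does not) depend on this exact shape.
#'
#' @param peak_time_s time to peak, s.
#' @param shape dimensionless shape exponent (larger = narrower transient).
#' @param support_s truncation point of the kernel, s.
#' @export
transient_settings <- function(peak_time_s = 35, shape = 3, support_s = 180) {
  if (peak_time_s <= 0 || shape <= 0 || support_s <= peak_time_s)
    stop_("invalid transient settings")
  structure(list(peak_time_s = peak_time_s, shape = shape,
                 support_s = support_s), class = "transient_settings")
}

pressor_kernel <- function(dt, tr) {
  out <- numeric(length(dt))
  ok <- dt > 0 & dt < tr$support_s
  u <- dt[ok] / tr$peak_time_s
  out[ok] <- u^tr$shape * exp(tr$shape * (1 - u))
  out
}

#' Simulate one beat-to-beat recording with bolus responses
#'
#' Generates beats sequentially: beat k+1 occurs \code{rri[k+1]} ms after beat
#' k. The systolic pressure of beat i is
#' \code{sbp_baseline + pressor(t_i) + noise}, where \code{pressor} sums the
#' active bolus transients; the RR interval ending at beat i+1 is
#' \code{60000/hr_baseline + b * (SBP_i - sbp_baseline) + noise}, with slope
#' \code{b} equal to the current bolus's per-bolus true slope (drawn around
#' \code{brs_true}). This makes the downstream regression structurally
#' unbiased: the RR interval responds to the realized (noisy) pressure, as in
#' the reflex itself. Generated RR intervals and pressures saturate at the
#' physiological bounds 300-2000 ms and 50-300 mmHg.
#'
#' @param params a \code{\link{condition_params}} object.
#' @param schedule a \code{\link{bolus_schedule}} object.
#' @param duration_s recording length, s; defaults to the schedule span plus
#'   one inter-bolus interval. Must cover every bolus plus 60 s.
#' @param seed integer seed; output is bit-reproducible given
#'   (params, schedule, seed).
#' @param transient a \code{\link{transient_settings}} object.
#' @return A list with elements \code{beats} (a \code{beat_series}
#'   data.frame: \code{beat_index}, \code{time_s}, \code{rri_ms},
#'   \code{sbp_mmhg}), \code{events} (a data.frame of class
#'   \code{bolus_events}: \code{bolus_index}, \code{time_s}, \code{dose_ug},
#'   \code{condition}), and \code{truth} (the per-bolus amplitudes and slopes
#'   actually drawn, for parameter-recovery testing).
#' @export
#' @examples
#' sim <- simulate_beats(condition_params(), bolus_schedule(n_boli = 2),
#'                       seed = 1)
#' head(sim$beats)
simulate_beats <- function(params, schedule, duration_s = NULL, seed,
                           transient = transient_settings()) {
  stopifnot(inherits(params, "condition_params"),
            inherits(schedule, "bolus_schedule"))
  bolus_times <- schedule$first_bolus_s +
    (seq_len(schedule$n_boli) - 1) * schedule$interval_s
  if (is.null(duration_s))
    duration_s <- max(bolus_times) + schedule$interval_s
  late <- which(bolus_times + 60 > duration_s)
  if (length(late))
    stop_("bolus %d at t = %g s extends beyond duration %g s (60 s of beats must follow each bolus)",
          late[1], bolus_times[late[1]], duration_s)

  set.seed(seed)
  rri0 <- 60000 / params$hr_baseline
  n_max <- ceiling(duration_s * 1000 / 300) + 2L
  rri_eps <- rnorm(n_max, 0, params$rri_noise_sd)
  sbp_eps <- rnorm(n_max, 0, params$sbp_noise_sd)
  amp <- rnorm_lower(schedule$n_boli, params$dsbp_true,
                     params$dsbp_between_sd, lower = 5)
  bslope <- pmax(0, params$brs_true +
                   rnorm(schedule$n_boli, 0, params$brs_between_sd))

  tp <- transient$peak_time_s
  sh <- transient$shape
  sup <- transient$support_s
  f_breath <- params$rr_breaths / 60     # Hz, for optional RSA
  rsa <- params$rsa_amplitude

  time <- numeric(n_max); rri <- numeric(n_max); sbp <- numeric(n_max)
  t <- 0; i <- 1L; j <- 0L
  rri_next <- clamp(rri0 + rri_eps[1L], 300, 2000)
  nb <- schedule$n_boli
  while (t <= duration_s && i <= n_max) {
    time[i] <- t
    rri[i] <- rri_next
    while (j < nb && bolus_times[j + 1L] <= t) j <- j + 1L
    press <- 0
    if (j > 0L) {
      for (k in max(1L, j - 2L):j) {
        dt <- t - bolus_times[k]
        if (dt > 0 && dt < sup) {
          u <- dt / tp
          press <- press + amp[k] * u^sh * exp(sh * (1 - u))
        }
      }
    }
    s <- params$sbp_baseline + press + sbp_eps[i]
    s <- if (s < 50) 50 else if (s > 300) 300 else s
    sbp[i] <- s
    b <- if (j > 0L) bslope[j] else params$brs_true
    r <- rri0 + b * (s - params$sbp_baseline) + rri_eps[i + 1L]
    if (rsa > 0) r <- r + rsa * sin(2 * pi * f_breath * t)
    rri_next <- if (r < 300) 300 else if (r > 2000) 2000 else r
    t <- t + rri_next / 1000
    i <- i + 1L
  }
  n <- i - 1L
  beats <- new_beat_series(
    data.frame(beat_index = seq_len(n), time_s = time[seq_len(n)],
               rri_ms = rri[seq_len(n)], sbp_mmhg = sbp[seq_len(n)]),
    subject_id = "sim", condition = params$label)
  events <- structure(
    data.frame(bolus_index = seq_len(nb), time_s = bolus_times,
               dose_ug = schedule$dose_ug, condition = params$label),
    class = c("bolus_events", "data.frame"))
  list(beats = beats, events = events,
       truth = list(params = params, amplitude = amp, slope = bslope))
}

#' Per-subject specification for a simulated cohort
#'
#' @param subject_id unique identifier.
#' @param normoxia,hypoxia \code{\link{condition_params}} for the two
#'   conditions.
#' @param schedule a \code{\link{bolus_schedule}} shared by both conditions.
#' @export
subject_spec <- function(subject_id, normoxia, hypoxia,
                         schedule = bolus_schedule()) {
  stopifnot(inherits(normoxia, "condition_params"),
            inherits(hypoxia, "condition_params"))
  if (normoxia$label != "normoxia" || hypoxia$label != "hypoxia")
    stop_("subject %s: condition labels must be normoxia and hypoxia",
          subject_id)
  structure(list(subject_id = as.character(subject_id), normoxia = normoxia,
                 hypoxia = hypoxia, schedule = schedule),
            class = "subject_spec")
}

#' Default nine-subject cohort specification
#'
#' Builds the simulator's default cohort from the packaged per-subject
#' reference summaries: each subject's true BRS and pressor amplitude per
#' condition equal the published per-subject means, and the bolus-to-bolus
#' dispersions equal the published SEM times sqrt(n) (the per-bolus SD the
#' summaries imply). Baseline pressure and heart rate use the published group
#' values (SBP 133/135 mmHg, HR 63/76 bpm for normoxia/hypoxia); respiratory
#' metadata come from the per-subject respiratory table, with normoxic SpO2
#' fixed at 98.1 percent and hypoxic SpO2 lowered by each subject's
#' desaturation.
#'
#' @param schedule bolus schedule applied to every subject-condition.
#' @return A list of \code{\link{subject_spec}} objects.
#' @export
reference_cohort_spec <- function(schedule = bolus_schedule()) {
  brs <- reference_summaries("brs")
  prs <- reference_summaries("pressor")
  rsp <- reference_summaries("respiratory")
  stopifnot(identical(brs$subject, prs$subject),
            identical(brs$subject, rsp$subject))
  lapply(seq_len(nrow(brs)), function(i) {
    subject_spec(
      subject_id = brs$subject[i],
      normoxia = condition_params(
        "normoxia", sbp_baseline = 133, hr_baseline = 63,
        brs_true = brs$brs_normoxia_mean[i],
        brs_between_sd = brs$brs_normoxia_sem[i] * sqrt(brs$brs_normoxia_n[i]),
        dsbp_true = prs$dsbp_normoxia_mean[i],
        dsbp_between_sd = prs$dsbp_normoxia_sem[i] * sqrt(prs$dsbp_normoxia_n[i]),
        spo2 = 98.1, ve = rsp$ve_normoxia[i], vt = rsp$vt_normoxia[i],
        rr_breaths = rsp$rr_normoxia[i], etco2 = 38.31),
      hypoxia = condition_params(
        "hypoxia", sbp_baseline = 135, hr_baseline = 76,
        brs_true = brs$brs_hypoxia_mean[i],
        brs_between_sd = brs$brs_hypoxia_sem[i] * sqrt(brs$brs_hypoxia_n[i]),
        dsbp_true = prs$dsbp_hypoxia_mean[i],
        dsbp_between_sd = prs$dsbp_hypoxia_sem[i] * sqrt(prs$dsbp_hypoxia_n[i]),
        spo2 = 98.1 - rsp$delta_spo2[i], ve = rsp$ve_hypoxia[i],
        vt = rsp$vt_hypoxia[i], rr_breaths = rsp$rr_hypoxia[i],
        etco2 = 37.78),
      schedule = schedule)
  })
}

#' Simulate a two-condition crossover cohort
#'
#' Each subject receives an independent random substream derived from
#' \code{seed} and a stable hash of the subject id, so adding, removing or
#' reordering subjects never changes another subject's data. Condition order
#' is randomized per subject (or alternates when \code{randomize_order =
#' FALSE}), mirroring the crossover randomization of the underlying protocol.
#'
#' @param cohort_spec list of \code{\link{subject_spec}} objects,
#'   e.g. \code{\link{reference_cohort_spec}()}.
#' @param seed integer master seed.
#' @param randomize_order randomize condition order per subject?
#' @param transient passed to \code{\link{simulate_beats}}.
#' @return A list of \code{subject_recording} objects, each with
#'   \code{subject_id}, \code{condition_order}, \code{beats} and
#'   \code{events} (named lists by condition), and \code{truth}.
#' @export
simulate_cohort <- function(cohort_spec, seed, randomize_order = TRUE,
                            transient = transient_settings()) {
  ids <- vapply(cohort_spec, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_("duplicate subject ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs <- lapply(cohort_spec, function(spec) {
    sseed <- child_seed(seed, string_seed(spec$subject_id))
    set.seed(sseed)
    first <- if (randomize_order) {
      if (runif(1) < 0.5) "normoxia" else "hypoxia"
    } else {
      c("normoxia", "hypoxia")[1L + string_seed(spec$subject_id) %% 2L]
    }
    ord <- c(first, setdiff(c("normoxia", "hypoxia"), first))
    sims <- lapply(c(normoxia = "normoxia", hypoxia = "hypoxia"), function(cc) {
      sim <- simulate_beats(spec[[cc]], spec$schedule,
                            seed = child_seed(sseed, match(cc, ord)),
                            transient = transient)
      attr(sim$beats, "subject_id") <- spec$subject_id
      sim$events$subject <- spec$subject_id
      sim
    })
    structure(list(subject_id = spec$subject_id, condition_order = ord,
                   beats = lapply(sims, `[[`, "beats"),
                   events = lapply(sims, `[[`, "events"),
                   truth = lapply(sims, `[[`, "truth")),
              class = "subject_recording")
  })
  names(recs) <- ids
  recs
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s  (first condition: %s)\n",
              x$subject_id, x$condition_order[1]))
  for (cc in names(x$beats))
    cat(sprintf("  %-9s %5d beats, %d boli\n", cc, nrow(x$beats[[cc]]),
                nrow(x$events[[cc]])))
  invisible(x)
}
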