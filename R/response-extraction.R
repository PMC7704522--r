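#' Extraction settings
#'
#' Tunable parameters of the per-bolus feature extraction. Defaults follow
#' the standard pharmacological (Oxford-style) analysis: baseline = mean of
#' the 10 beats immediately before the bolus; peak = best mean of 3
#' consecutive systolic values within 60 s after the bolus; BRS = slope of
#' RR interval (one beat later, \code{lag = 1}) on systolic pressure over the
#' rise phase, accepted when Pearson's r exceeds 0.5 (strictly).
#'
#' @param baseline_beats number of pre-bolus beats averaged for baseline SBP.
#' @param peak_window_s length of the post-bolus peak search window, s.
#' @param peak_run consecutive beats averaged for the peak.
#' @param r_threshold acceptance threshold on Pearson's r (strict >).
#' @param min_pairs minimum rise-phase pairs for a slope to be reported.
#' @param lag beat lag pairing SBP_i with RRI_(i+lag); one of 0, 1, 2.
#' @param onset_k rise-phase onset: first post-bolus beat whose SBP exceeds
#'   baseline + \code{onset_k} * SD of the baseline beats.
#' @export
extraction_settings <- function(baseline_beats = 10, peak_window_s = 60,
                                peak_run = 3, r_threshold = 0.5,
                                min_pairs = 5, lag = 1, onset_k = 2) {
  if (!lag %in% 0:2) stop_("lag must be 0, 1 or 2")
  if (baseline_beats < 2 || peak_run < 1 || min_pairs < 2)
    stop_("degenerate extraction settings")
  structure(list(baseline_beats = as.integer(baseline_beats),
                 peak_window_s = peak_window_s,
                 peak_run = as.integer(peak_run), r_threshold = r_threshold,
                 min_pairs = as.integer(min_pairs), lag = as.integer(lag),
                 onset_k = onset_k), class = "extraction_settings")
}

# Indices of the `n` beats immediately preceding the bolus (strictly earlier).
pre_bolus_idx <- function(beats, bolus_time, n) {
  last_pre <- findInterval(bolus_time, beats$time_s, left.open = TRUE)
  if (last_pre < n)
    stop_("bolus at t = %g s: only %d pre-bolus beats, %d required",
          bolus_time, max(last_pre, 0L), n)
  (last_pre - n + 1L):last_pre
}

#' Baseline systolic pressure before a bolus
#'
#' Arithmetic mean of the systolic pressure of the beats immediately
#' preceding the bolus (default 10, per the standard definition).
#'
#' @param beats a \code{\link{beat_series}}.
#' @param bolus_time bolus injection time, s (or a one-row events data.frame).
#' @param settings an \code{\link{extraction_settings}} object.
#' @return Baseline SBP, mmHg.
#' @export
baseline_sbp <- function(beats, bolus_time, settings = extraction_settings()) {
  bolus_time <- bolus_time_of(bolus_time)
  idx <- pre_bolus_idx(beats, bolus_time, settings$baseline_beats)
  mean(beats$sbp_mmhg[idx])
}

bolus_time_of <- function(x) {
  if (is.data.frame(x)) x$time_s[1] else x
}

#' Peak systolic pressure after a bolus
#'
#' Slides a window of \code{peak_run} consecutive beats over the post-bolus
#' beats whose times fall within \code{(t_bolus, t_bolus + peak_window_s]} and
#' returns the maximal window mean; ties are broken by the earliest window.
#'
#' @inheritParams baseline_sbp
#' @return A list: \code{sbp_peak} (mmHg), \code{peak_time_s} (time of the
#'   central beat of the winning window), \code{peak_index} (its beat index).
#' @export
peak_sbp <- function(beats, bolus_time, settings = extraction_settings()) {
  bolus_time <- bolus_time_of(bolus_time)
  t <- beats$time_s
  lo <- findInterval(bolus_time, t, left.open = FALSE) + 1L
  # beats strictly after the bolus ...
  while (lo <= length(t) && t[lo] <= bolus_time) lo <- lo + 1L
  hi <- findInterval(bolus_time + settings$peak_window_s, t)
  k <- settings$peak_run
  if (hi - lo + 1L < k)
    stop_("bolus at t = %g s: fewer than %d beats in the %g s peak window",
          bolus_time, k, settings$peak_window_s)
  s <- beats$sbp_mmhg[lo:hi]
  win <- filter_mean(s, k)
  best <- which.max(win)                    # which.max takes the first maximum
  centre <- lo + best - 1L + (k - 1L) %/% 2L
  list(sbp_peak = win[best], peak_time_s = t[centre], peak_index = centre)
}

# Rolling mean of k consecutive values; returns length(x) - k + 1 means.
filter_mean <- function(x, k) {
  cs <- cumsum(c(0, x))
  (cs[(k + 1L):length(cs)] - cs[1:(length(cs) - k)]) / k
}

#' Cardiovagal BRS from one bolus (Oxford regression)
#'
#' Ordinary least squares of the RR interval \code{lag} beats later on the
#' systolic pressure of each rise-phase beat. The rise phase runs from the
#' first post-bolus beat whose SBP exceeds baseline + \code{onset_k} times
#' the baseline-beat SD, up to and including the central beat of the peak
#' window. Returns a no-slope result (NA slope, reason recorded) when fewer
#' than \code{min_pairs} pairs are available or the pressures have zero
#' variance.
#'
#' @inheritParams baseline_sbp
#' @return A list: \code{slope} (ms/mmHg), \code{intercept} (ms), \code{r}
#'   (Pearson), \code{n} (pairs used), \code{pairs} (beat indices of the
#'   rise-phase SBP values used), \code{reason} (NA or why no slope).
#' @export
estimate_brs <- function(beats, bolus_time, settings = extraction_settings()) {
  bolus_time <- bolus_time_of(bolus_time)
  base_idx <- pre_bolus_idx(beats, bolus_time, settings$baseline_beats)
  base <- mean(beats$sbp_mmhg[base_idx])
  base_sd <- sd(beats$sbp_mmhg[base_idx])
  pk <- peak_sbp(beats, bolus_time, settings)

  first_post <- base_idx[length(base_idx)] + 1L
  onset <- first_post
  thresh <- base + settings$onset_k * base_sd
  while (onset <= pk$peak_index && beats$sbp_mmhg[onset] <= thresh)
    onset <- onset + 1L
  no_slope <- function(reason, n = 0L)
    list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
         n = as.integer(n), pairs = integer(0), reason = reason)
  if (onset > pk$peak_index) return(no_slope("no rise above onset threshold"))
  idx <- onset:pk$peak_index
  idx <- idx[idx + settings$lag <= nrow(beats)]
  if (length(idx) < settings$min_pairs)
    return(no_slope(sprintf("only %d rise-phase pairs (minimum %d)",
                            length(idx), settings$min_pairs), length(idx)))
  x <- beats$sbp_mmhg[idx]
  y <- beats$rri_ms[idx + settings$lag]
  if (var(x) == 0) return(no_slope("zero SBP variance in rise phase",
                                   length(idx)))
  slope <- cov(x, y) / var(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = if (var(y) == 0) NA_real_ else cor(x, y),
       n = length(idx), pairs = idx, reason = NA_character_)
}

# Acceptance rule for a regression: strictly greater than the threshold.
slope_accepted <- function(r, threshold = 0.5) {
  !is.na(r) && r > threshold
}

#' Extract all per-bolus features for one bolus
#'
#' Assembles baseline, peak, delta-SBP and the BRS regression into one row.
#' A bolus whose regression fails the r criterion (or yields no slope) is
#' never dropped: it is carried with \code{accepted = FALSE} so that the
#' number of boli analyzed can differ between the BRS and pressor metrics,
#' as in real recordings where not every administration yields a response
#' suitable for baroreflex analysis.
#'
#' @inheritParams baseline_sbp
#' @return One-row data.frame: \code{bolus_index}, \code{time_s},
#'   \code{sbp_baseline}, \code{sbp_peak}, \code{peak_time_s},
#'   \code{delta_sbp}, \code{brs_slope}, \code{brs_intercept},
#'   \code{pearson_r}, \code{n_beats_regression}, \code{accepted},
#'   \code{reject_reason}.
#' @export
extract_bolus_response <- function(beats, bolus,
                                   settings = extraction_settings()) {
  stopifnot(is.data.frame(bolus), nrow(bolus) == 1L)
  base <- baseline_sbp(beats, bolus$time_s, settings)
  pk <- peak_sbp(beats, bolus$time_s, settings)
  reg <- estimate_brs(beats, bolus$time_s, settings)
  accepted <- slope_accepted(reg$r, settings$r_threshold)
  data.frame(
    bolus_index = bolus$bolus_index, time_s = bolus$time_s,
    sbp_baseline = base, sbp_peak = pk$sbp_peak,
    peak_time_s = pk$peak_time_s, delta_sbp = pk$sbp_peak - base,
    brs_slope = reg$slope, brs_intercept = reg$intercept,
    pearson_r = reg$r, n_beats_regression = reg$n,
    accepted = accepted,
    reject_reason = if (accepted) NA_character_ else
      if (!is.na(reg$reason)) reg$reason else
        sprintf("r = %.3f <= %.2f", reg$r, settings$r_threshold),
    stringsAsFactors = FALSE)
}

#' Extract per-bolus responses for a whole condition
#'
#' Applies \code{\link{extract_bolus_response}} to every bolus of one
#' subject-condition recording. Errors if the analysis windows of adjacent
#' boli overlap (the baseline beats of bolus k+1 must all lie after the
#' 60 s peak window of bolus k).
#'
#' @param beats a \code{\link{beat_series}}.
#' @param events a bolus events data.frame (\code{bolus_index},
#'   \code{time_s}, ...), sorted by time.
#' @param settings an \code{\link{extraction_settings}} object.
#' @return A \code{bolus_responses} data.frame, one row per bolus, with
#'   \code{subject} and \code{condition} columns prepended.
#' @export
extract_condition <- function(beats, events,
                              settings = extraction_settings()) {
  if (nrow(events) == 0L) return(empty_responses())
  if (is.unsorted(events$time_s, strictly = TRUE))
    stop_("bolus events must be sorted by strictly increasing time")
  for (k in seq_len(nrow(events) - 1L)) {
    nxt_base <- pre_bolus_idx(beats, events$time_s[k + 1L],
                              settings$baseline_beats)
    if (beats$time_s[nxt_base[1]] <= events$time_s[k] + settings$peak_window_s)
      stop_("analysis windows of boli %d and %d overlap: baseline beats of bolus %d begin at t = %.1f s, inside the %g s peak window of bolus %d",
            k, k + 1L, k + 1L, beats$time_s[nxt_base[1]],
            settings$peak_window_s, k)
  }
  rows <- lapply(seq_len(nrow(events)), function(k)
    extract_bolus_response(beats, events[k, , drop = FALSE], settings))
  out <- do.call(rbind, rows)
  out <- cbind(subject = attr(beats, "subject_id"),
               condition = attr(beats, "condition"), out,
               stringsAsFactors = FALSE)
  class(out) <- c("bolus_responses", "data.frame")
  out
}

empty_responses <- function() {
  out <- data.frame(subject = character(), condition = character(),
                    bolus_index = integer(), time_s = numeric(),
                    sbp_baseline = numeric(), sbp_peak = numeric(),
                    peak_time_s = numeric(), delta_sbp = numeric(),
                    brs_slope = numeric(), brs_intercept = numeric(),
                    pearson_r = numeric(), n_beats_regression = integer(),
                    accepted = logical(), reject_reason = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("bolus_responses", "data.frame")
  out
}

#' Extract responses for every subject and condition of a simulated cohort
#'
#' @param recordings list of \code{subject_recording} objects from
#'   \code{\link{simulate_cohort}}.
#' @param settings an \code{\link{extraction_settings}} object.
#' @return A single \code{bolus_responses} data.frame.
#' @export
extract_cohort <- function(recordings, settings = extraction_settings()) {
  out <- do.call(rbind, unlist(lapply(recordings, function(rec)
    lapply(names(rec$beats), function(cc)
      extract_condition(rec$beats[[cc]], rec$events[[cc]], settings))),
    recursive = FALSE))
  class(out) <- c("bolus_responses", "data.frame")
  out
}
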