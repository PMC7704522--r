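#' Per-subject condition statistic over accepted boli
#'
#' The cohort-level analysis condenses each subject-condition to one number.
#' Medians of up to 20 boli are used for the paired group test (robust to
#' occasional outlier boli); means with SEM are used for table display. Both
#' are available here under the \code{statistic} switch; an even-count
#' median is the midpoint of the two central order statistics.
#'
#' @param responses a \code{bolus_responses} data.frame for one
#'   subject-condition.
#' @param metric \code{"brs"} or \code{"delta_sbp"}.
#' @param statistic \code{"median"} or \code{"mean"}.
#' @return A list: \code{value}, \code{sem} (0 when a single value),
#'   \code{n}.
#' @export
condition_statistic <- function(responses, metric = c("brs", "delta_sbp"),
                                statistic = c("median", "mean")) {
  metric <- match.arg(metric)
  statistic <- match.arg(statistic)
  s <- metric_sample(responses, metric)
  if (s$n < 1)
    stop_("subject %s, condition %s: no accepted boli for metric %s",
          s$subject, s$condition, metric)
  list(value = if (statistic == "median") median(s$values) else s$mean,
       sem = s$sem, n = s$n)
}

#' Paired cohort comparison of per-subject statistics
#'
#' Paired t test of the subject-aligned per-subject statistics (hypoxia minus
#' normoxia), with the cohort means and SEMs of both conditions for display.
#'
#' @param per_subject_norm,per_subject_hyp numeric vectors of per-subject
#'   statistics, aligned by subject (same order, same length, n >= 2).
#' @param subjects optional subject ids for alignment checking.
#' @param metric metric label carried in the result.
#' @return A \code{group_result} list: per-subject vectors, group means and
#'   SEMs per condition, \code{mean_difference} and \code{sem_difference}
#'   (hypoxia - normoxia), \code{paired_t}, \code{df}, \code{p}. When all
#'   paired differences are identical the SEM is zero and the test is
#'   degenerate: t is 0 (difference zero) or +/-Inf, flagged via
#'   \code{degenerate = TRUE}.
#' @export
paired_group_test <- function(per_subject_norm, per_subject_hyp,
                              subjects = NULL, metric = "brs") {
  n <- length(per_subject_norm)
  if (length(per_subject_hyp) != n)
    stop_("misaligned condition vectors: %d vs %d subjects", n,
          length(per_subject_hyp))
  if (n < 2) stop_("paired test requires at least 2 subjects")
  if (!is.null(subjects) && anyDuplicated(subjects))
    stop_("duplicate subjects")
  d <- per_subject_hyp - per_subject_norm
  md <- mean(d)
  sd_d <- sd(d)
  degenerate <- sd_d == 0
  if (degenerate) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    tt <- t.test(per_subject_hyp, per_subject_norm, paired = TRUE)
    t <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    metric = metric, subjects = subjects,
    per_subject_normoxia = per_subject_norm,
    per_subject_hypoxia = per_subject_hyp,
    group_mean_normoxia = mean(per_subject_norm),
    group_sem_normoxia = sem(per_subject_norm),
    group_mean_hypoxia = mean(per_subject_hyp),
    group_sem_hypoxia = sem(per_subject_hyp),
    mean_difference = md, sem_difference = sd_d / sqrt(n),
    paired_t = t, df = n - 1L, p = p, degenerate = degenerate),
    class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: normoxia %.2f +/- %.2f vs hypoxia %.2f +/- %.2f (n = %d)\n",
              x$metric, x$group_mean_normoxia, x$group_sem_normoxia,
              x$group_mean_hypoxia, x$group_sem_hypoxia,
              length(x$per_subject_normoxia)))
  cat(sprintf("  paired difference %.2f +/- %.2f, t(%d) = %.3f, p = %.4g\n",
              x$mean_difference, x$sem_difference, x$df, x$paired_t, x$p))
  invisible(x)
}

#' Cohort-level analysis of a responses table
#'
#' Condenses each subject-condition with \code{\link{condition_statistic}}
#' and runs the paired group test for one metric.
#'
#' @param responses a \code{bolus_responses} data.frame covering both
#'   conditions of several subjects.
#' @param metric \code{"brs"} or \code{"delta_sbp"}.
#' @param statistic per-subject statistic for the paired test
#'   (\code{"median"} by default, as in the robust group analysis).
#' @return A \code{group_result}.
#' @export
group_analysis <- function(responses, metric = c("brs", "delta_sbp"),
                           statistic = c("median", "mean")) {
  metric <- match.arg(metric)
  statistic <- match.arg(statistic)
  subjects <- sort(unique(responses$subject))
  per_cond <- function(cc) vapply(subjects, function(s) {
    condition_statistic(
      responses[responses$subject == s & responses$condition == cc, ,
                drop = FALSE], metric, statistic)$value
  }, numeric(1))
  paired_group_test(per_cond("normoxia"), per_cond("hypoxia"),
                    subjects = subjects, metric = metric)
}

#' Correlation of per-subject changes in two metrics
#'
#' Pearson correlation between the per-subject condition differences of two
#' metrics (e.g. change in BRS vs change in pressor response), testing
#' whether impaired cardiovagal gain and impaired blood pressure buffering
#' travel together across individuals.
#'
#' @param delta_x,delta_y aligned per-subject change vectors (n >= 3).
#' @return A list: \code{r}, \code{p}, \code{n}, and \code{undefined}
#'   (TRUE when either vector has zero variance, in which case r is NA).
#' @export
correlate_changes <- function(delta_x, delta_y) {
  n <- length(delta_x)
  if (length(delta_y) != n) stop_("misaligned change vectors")
  if (n < 3) stop_("correlation requires at least 3 subjects")
  if (sd(delta_x) == 0 || sd(delta_y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  ct <- cor.test(delta_x, delta_y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
}
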