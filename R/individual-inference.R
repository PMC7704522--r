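#' Unpaired t statistic from summary statistics
#'
#' Welch's unequal-variance t test computed purely from the six printed
#' summaries (mean, SEM, n per arm), so that published per-subject table rows
#' can be checked directly: \code{t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p value.
#' With \code{pooled = TRUE} the classical equal-variance test is used
#' instead (the two coincide when SEMs and n are equal).
#'
#' @param mean1,sem1,n1 first arm: mean, standard error of the mean, count.
#' @param mean2,sem2,n2 second arm.
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return A list: \code{t}, \code{df}, \code{p}, \code{se} (standard error
#'   of the mean difference). Degenerate inputs: both SEMs zero with equal
#'   means gives \code{t = 0, p = 1}; with unequal means \code{t = +/-Inf,
#'   p = 0}.
#' @export
#' @examples
#' welch_t_from_summary(14.4, 0.8, 20, 8.3, 0.8, 20)  # t approx 5.39
welch_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                                 pooled = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 >= 0, sem2 >= 0)
  diff <- mean1 - mean2
  if (sem1 == 0 && sem2 == 0) {
    if (diff == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1, se = 0))
    return(list(t = sign(diff) * Inf, df = n1 + n2 - 2, p = 0, se = 0))
  }
  if (pooled) {
    s2p <- ((n1 - 1) * sem1^2 * n1 + (n2 - 1) * sem2^2 * n2) / (n1 + n2 - 2)
    se <- sqrt(s2p * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sem1^2 + sem2^2)
    df <- se^4 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  }
  t <- diff / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), se = se)
}

#' Per-bolus metric sample for one subject-condition
#'
#' Collects the per-bolus values of one metric from a responses table. For
#' \code{"brs"} only accepted regressions contribute; for \code{"delta_sbp"}
#' every bolus with a valid baseline/peak contributes, even when its BRS
#' regression was rejected, so the two metrics can have different n.
#'
#' @param responses a \code{bolus_responses} data.frame (one
#'   subject-condition).
#' @param metric \code{"brs"} or \code{"delta_sbp"}.
#' @return A \code{metric_sample} list: \code{subject}, \code{condition},
#'   \code{metric}, \code{values}, \code{n}, \code{mean}, \code{sem}.
#' @export
metric_sample <- function(responses, metric = c("brs", "delta_sbp")) {
  metric <- match.arg(metric)
  values <- if (metric == "brs") {
    responses$brs_slope[responses$accepted]
  } else {
    responses$delta_sbp[!is.na(responses$delta_sbp)]
  }
  values <- values[!is.na(values)]
  structure(list(subject = unique(responses$subject)[1],
                 condition = unique(responses$condition)[1],
                 metric = metric, values = values, n = length(values),
                 mean = mean(values), sem = sem(values)),
            class = "metric_sample")
}

#' N-of-1 comparison of one metric between conditions
#'
#' Unpaired (Welch by default) t test of the per-bolus values of one subject
#' under hypoxia versus normoxia. The reported difference is hypoxia minus
#' normoxia, so a negative BRS difference means the baroreflex slope fell
#' under chemoreflex activation. Classification at level \code{alpha}:
#' \code{"decreased"} if p < alpha and the difference is negative,
#' \code{"increased"} if p < alpha and positive, otherwise
#' \code{"unchanged"}.
#'
#' @param sample_norm,sample_hyp \code{\link{metric_sample}} objects for the
#'   same subject and metric.
#' @param alpha significance level.
#' @param pooled use the pooled-variance test.
#' @return An \code{individual_comparison} one-row data.frame with means,
#'   SEMs and n per condition, the difference, t, df, p, the 95\% CI of the
#'   difference, and the classification.
#' @export
compare_individual <- function(sample_norm, sample_hyp, alpha = 0.05,
                               pooled = FALSE) {
  stopifnot(inherits(sample_norm, "metric_sample"),
            inherits(sample_hyp, "metric_sample"))
  if (!identical(sample_norm$metric, sample_hyp$metric))
    stop_("metric mismatch: %s vs %s", sample_norm$metric, sample_hyp$metric)
  if (!identical(sample_norm$subject, sample_hyp$subject))
    stop_("subject mismatch: %s vs %s", sample_norm$subject,
          sample_hyp$subject)
  for (s in list(sample_norm, sample_hyp))
    if (s$n < 2)
      stop_("subject %s, metric %s, condition %s: %d value(s); at least 2 per-bolus values required",
            s$subject, s$metric, s$condition, s$n)
  w <- welch_t_from_summary(sample_hyp$mean, sample_hyp$sem, sample_hyp$n,
                            sample_norm$mean, sample_norm$sem, sample_norm$n,
                            pooled = pooled)
  diff <- sample_hyp$mean - sample_norm$mean
  ci <- if (w$se > 0) diff + c(-1, 1) * qt(0.975, w$df) * w$se else c(diff, diff)
  classification <- if (w$p < alpha && diff < 0) "decreased"
    else if (w$p < alpha && diff > 0) "increased" else "unchanged"
  out <- data.frame(
    subject = sample_norm$subject, metric = sample_norm$metric,
    mean_normoxia = sample_norm$mean, sem_normoxia = sample_norm$sem,
    n_normoxia = sample_norm$n, mean_hypoxia = sample_hyp$mean,
    sem_hypoxia = sample_hyp$sem, n_hypoxia = sample_hyp$n,
    difference = diff, t_statistic = w$t, degrees_of_freedom = w$df,
    p_value = w$p, ci95_low = ci[1], ci95_high = ci[2],
    classification = classification, stringsAsFactors = FALSE)
  class(out) <- c("individual_comparison", "data.frame")
  out
}

#' Individual comparisons for every subject of a cohort responses table
#'
#' @param responses a \code{bolus_responses} data.frame covering both
#'   conditions of one or more subjects.
#' @param metric \code{"brs"} or \code{"delta_sbp"}.
#' @param alpha significance level.
#' @param pooled use the pooled-variance test.
#' @param p_adjust optional p-value adjustment method across subjects
#'   (see \code{\link[stats]{p.adjust}}); \code{"none"} by default, matching
#'   per-subject testing at alpha without correction.
#' @return An \code{individual_comparison} data.frame, one row per subject.
#' @export
compare_cohort <- function(responses, metric = c("brs", "delta_sbp"),
                           alpha = 0.05, pooled = FALSE, p_adjust = "none") {
  metric <- match.arg(metric)
  rows <- lapply(split(responses, responses$subject), function(rs) {
    compare_individual(
      metric_sample(rs[rs$condition == "normoxia", , drop = FALSE], metric),
      metric_sample(rs[rs$condition == "hypoxia", , drop = FALSE], metric),
      alpha = alpha, pooled = pooled)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
    out$classification <- ifelse(out$p_value < alpha,
                                 ifelse(out$difference < 0, "decreased",
                                        "increased"), "unchanged")
  }
  class(out) <- c("individual_comparison", "data.frame")
  out
}

#' Individual comparisons from a printed summary table
#'
#' Reconstructs each subject's unpaired test directly from published
#' mean/SEM/n rows (no raw per-bolus values needed), using
#' \code{\link{welch_t_from_summary}} and the same classification rule as
#' \code{\link{compare_individual}}.
#'
#' @param summaries a data.frame in the layout of
#'   \code{\link{reference_summaries}} (\code{"brs"} or \code{"pressor"}).
#' @param metric metric name recorded in the output.
#' @param alpha significance level.
#' @param pooled use the pooled-variance test.
#' @return An \code{individual_comparison} data.frame, one row per subject.
#' @export
compare_from_summary <- function(summaries, metric = c("brs", "delta_sbp"),
                                 alpha = 0.05, pooled = FALSE) {
  metric <- match.arg(metric)
  pre <- if (metric == "brs") "brs" else "dsbp"
  col <- function(cc, f) summaries[[paste(pre, cc, f, sep = "_")]]
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    w <- welch_t_from_summary(col("hypoxia", "mean")[i],
                              col("hypoxia", "sem")[i],
                              col("hypoxia", "n")[i],
                              col("normoxia", "mean")[i],
                              col("normoxia", "sem")[i],
                              col("normoxia", "n")[i], pooled = pooled)
    diff <- col("hypoxia", "mean")[i] - col("normoxia", "mean")[i]
    ci <- if (w$se > 0) diff + c(-1, 1) * qt(0.975, w$df) * w$se
          else c(diff, diff)
    data.frame(subject = summaries$subject[i], metric = metric,
               mean_normoxia = col("normoxia", "mean")[i],
               sem_normoxia = col("normoxia", "sem")[i],
               n_normoxia = col("normoxia", "n")[i],
               mean_hypoxia = col("hypoxia", "mean")[i],
               sem_hypoxia = col("hypoxia", "sem")[i],
               n_hypoxia = col("hypoxia", "n")[i],
               difference = diff, t_statistic = w$t,
               degrees_of_freedom = w$df, p_value = w$p,
               ci95_low = ci[1], ci95_high = ci[2],
               classification = if (w$p < alpha && diff < 0) "decreased"
                 else if (w$p < alpha && diff > 0) "increased"
                 else "unchanged",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("individual_comparison", "data.frame")
  out
}

#' Tally individual classifications across a cohort
#'
#' @param comparisons an \code{individual_comparison} data.frame, one row per
#'   subject (duplicate subjects are an error).
#' @return Named integer vector: \code{decreased}, \code{increased},
#'   \code{unchanged}.
#' @export
classify_cohort <- function(comparisons) {
  if (anyDuplicated(comparisons$subject))
    stop_("duplicate subjects in comparisons: %s",
          paste(unique(comparisons$subject[duplicated(comparisons$subject)]),
                collapse = ", "))
  counts <- table(factor(comparisons$classification,
                         levels = c("decreased", "increased", "unchanged")))
  setNames(as.integer(counts), names(counts))
}
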