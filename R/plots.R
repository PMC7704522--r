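# Figures. All return ggplot objects; the pipeline saves them as PDF.

#' Forest plot of individual condition differences
#'
#' One row per subject: mean difference (hypoxia - normoxia) with its 95\%
#' confidence interval, annotated with the p value; the dashed line marks no
#' change.
#'
#' @param comparisons an \code{individual_comparison} data.frame.
#' @return A ggplot object.
#' @export
plot_forest <- function(comparisons) {
  df <- as.data.frame(comparisons)
  df$subject <- factor(df$subject, levels = rev(sort(unique(df$subject))))
  unit <- if (df$metric[1] == "brs") "ms/mmHg" else "mmHg"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference, y = .data$subject)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci95_low,
                                         xmax = .data$ci95_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$classification), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.3f", .data$p_value)),
                       vjust = -1, size = 2.8) +
    ggplot2::labs(x = sprintf("Difference hypoxia - normoxia (%s)", unit),
                  y = "Subject",
                  title = sprintf("Individual %s changes",
                                  toupper(df$metric[1]))) +
    ggplot2::theme_minimal()
}

#' Scatter of per-subject changes in BRS vs pressor response
#'
#' @param delta_brs,delta_dsbp aligned per-subject change vectors.
#' @param subjects optional labels.
#' @return A ggplot object.
#' @export
plot_change_correlation <- function(delta_brs, delta_dsbp, subjects = NULL) {
  df <- data.frame(delta_brs = delta_brs, delta_dsbp = delta_dsbp,
                   subject = subjects %||% seq_along(delta_brs))
  cc <- correlate_changes(delta_brs, delta_dsbp)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_brs, .data$delta_dsbp)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Change in BRS (ms/mmHg)",
                  y = "Change in pressor response (mmHg)",
                  title = sprintf("r = %.2f, p = %.2f", cc$r, cc$p)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Per-subject condition lines for one metric
#'
#' @param group a \code{group_result}.
#' @return A ggplot object.
#' @export
plot_group_lines <- function(group) {
  n <- length(group$per_subject_normoxia)
  df <- data.frame(
    subject = rep(group$subjects %||% seq_len(n), 2),
    condition = factor(rep(c("normoxia", "hypoxia"), each = n),
                       levels = c("normoxia", "hypoxia")),
    value = c(group$per_subject_normoxia, group$per_subject_hypoxia))
  unit <- if (group$metric == "brs") "ms/mmHg" else "mmHg"
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$value,
                                   group = .data$subject)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(y = sprintf("%s (%s)", toupper(group$metric), unit),
                  x = NULL,
                  title = sprintf("%s: paired p = %.3g", toupper(group$metric),
                                  group$p)) +
    ggplot2::theme_minimal()
}

#' Sensitivity-versus-repetitions curve
#'
#' @param ... one or more \code{plan_result} objects (e.g. the two decision
#'   readings side by side).
#' @return A ggplot object.
#' @export
plot_sensitivity_curve <- function(...) {
  results <- list(...)
  df <- do.call(rbind, lapply(results, function(r)
    cbind(r$curve, method = r$spec$method)))
  target <- results[[1]]$spec$target_sensitivity
  ggplot2::ggplot(df, ggplot2::aes(.data$n_boli, .data$sensitivity,
                                   colour = .data$method)) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$sensitivity - 2 * .data$mc_se),
      ymax = pmin(1, .data$sensitivity + 2 * .data$mc_se))) +
    ggplot2::labs(x = "Boli per condition", y = "Sensitivity") +
    ggplot2::theme_minimal()
}
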