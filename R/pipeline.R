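#' Run the full simulate-extract-analyze-plan pipeline
#'
#' Executes every stage in order against a simulated cohort and writes a
#' report bundle into \code{out_dir}:
#' \itemize{
#'   \item \code{beats/<subject>_<condition>_{beats,events}.csv} -- the
#'     simulated recordings;
#'   \item \code{responses.csv} -- per-bolus features;
#'   \item \code{individual.csv} -- per-subject comparisons for both metrics;
#'   \item \code{group.csv} -- cohort-level paired results;
#'   \item \code{changes_correlation.csv} -- BRS-change vs pressor-change
#'     correlation;
#'   \item \code{plan.csv} -- sensitivity-versus-repetitions curve;
#'   \item \code{figures/*.pdf} -- forest plots, group lines, correlation and
#'     planning figures;
#'   \item \code{run_log.txt} -- config hash, seed, per-stage record counts
#'     and per-bolus rejection reasons.
#' }
#' CSV outputs are byte-identical across runs with the same config and seed.
#' A stage failure aborts with the failing stage named.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param figures write PDF figures (set FALSE for headless speed)?
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, figures = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "beats"), showWarnings = FALSE)
  log_lines <- c(sprintf("baroN1 %s", packageVersion("baroN1")),
                 sprintf("config_hash %s", config_hash(config)),
                 sprintf("seed %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  schedule <- do.call(bolus_schedule, config$schedule)
  settings <- do.call(extraction_settings, config$extraction)
  spec <- cohort_spec_from_config(config$cohort)

  recordings <- stage("simulate", {
    spec <- lapply(spec, function(s) { s$schedule <- schedule; s })
    simulate_cohort(spec, seed = config$seed)
  })
  for (rec in recordings)
    for (cc in names(rec$beats)) {
      stem <- file.path(out_dir, "beats", paste0(rec$subject_id, "_", cc))
      write_beats(rec$beats[[cc]], paste0(stem, "_beats.csv"), config)
      write_events(rec$events[[cc]], paste0(stem, "_events.csv"), config)
    }
  log_lines <- c(log_lines, sprintf("simulate: %d subjects, %d boli/condition",
                                    length(recordings), schedule$n_boli))

  responses <- stage("extract", extract_cohort(recordings, settings))
  write_responses(responses, file.path(out_dir, "responses.csv"), config)
  rej <- responses$reject_reason[!responses$accepted]
  log_lines <- c(log_lines,
                 sprintf("extract: %d responses, %d rejected for BRS",
                         nrow(responses), sum(!responses$accepted)),
                 sprintf("  rejection[%s]: %d", names(table(rej)), table(rej)))

  alpha <- config$statistics$alpha
  individual <- stage("analyze_individual", rbind(
    compare_cohort(responses, "brs", alpha, config$statistics$pooled,
                   config$statistics$p_adjust),
    compare_cohort(responses, "delta_sbp", alpha, config$statistics$pooled,
                   config$statistics$p_adjust)))
  write_csv_commented(individual, file.path(out_dir, "individual.csv"),
                      std_comments(config))
  log_lines <- c(log_lines, sprintf("analyze_individual: %d comparisons",
                                    nrow(individual)))

  groups <- stage("analyze_group", list(
    brs = group_analysis(responses, "brs"),
    delta_sbp = group_analysis(responses, "delta_sbp")))
  group_df <- do.call(rbind, lapply(groups, function(g)
    data.frame(metric = g$metric, group_mean_normoxia = g$group_mean_normoxia,
               group_sem_normoxia = g$group_sem_normoxia,
               group_mean_hypoxia = g$group_mean_hypoxia,
               group_sem_hypoxia = g$group_sem_hypoxia,
               mean_difference = g$mean_difference,
               sem_difference = g$sem_difference, paired_t = g$paired_t,
               df = g$df, p = g$p)))
  write_csv_commented(group_df, file.path(out_dir, "group.csv"),
                      std_comments(config))
  ind_brs <- individual[individual$metric == "brs", ]
  ind_dsbp <- individual[individual$metric == "delta_sbp", ]
  corr <- stage("analyze_correlation",
                if (nrow(ind_brs) >= 3)
                  correlate_changes(ind_brs$difference, ind_dsbp$difference)
                else list(r = NA_real_, p = NA_real_, n = nrow(ind_brs),
                          undefined = TRUE))
  write_csv_commented(data.frame(r = corr$r, p = corr$p, n = corr$n),
                      file.path(out_dir, "changes_correlation.csv"),
                      std_comments(config))
  log_lines <- c(log_lines,
                 sprintf("analyze_group: %s paired p = %.4g",
                         names(groups), vapply(groups, `[[`, 0, "p")),
                 sprintf("correlation of changes: r = %.3f, p = %.3f",
                         corr$r, corr$p))

  plan <- stage("plan", sensitivity_curve(do.call(plan_spec, config$plan),
                                          seed = config$seed))
  write_csv_commented(plan$curve, file.path(out_dir, "plan.csv"),
                      std_comments(config))
  log_lines <- c(log_lines,
                 sprintf("plan: minimal n = %s for target sensitivity %.2f",
                         plan$minimal_n, plan$spec$target_sensitivity))

  if (figures) {
    figdir <- file.path(out_dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    save_fig <- function(p, name)
      suppressMessages(ggplot2::ggsave(file.path(figdir, name), p,
                                       width = 6, height = 5))
    stage("report", {
      save_fig(plot_forest(ind_brs), "forest_brs.pdf")
      save_fig(plot_forest(ind_dsbp), "forest_delta_sbp.pdf")
      save_fig(plot_group_lines(groups$brs), "group_brs.pdf")
      save_fig(plot_group_lines(groups$delta_sbp), "group_delta_sbp.pdf")
      if (nrow(ind_brs) >= 3)
        save_fig(plot_change_correlation(ind_brs$difference,
                                         ind_dsbp$difference,
                                         ind_brs$subject),
                 "changes_correlation.pdf")
      save_fig(plot_sensitivity_curve(plan), "sensitivity_curve.pdf")
    })
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(recordings = recordings, responses = responses,
                 individual = individual, groups = groups,
                 correlation = corr, plan = plan, log = log_lines))
}
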