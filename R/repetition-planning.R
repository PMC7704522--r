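#' Plan specification for the repetition-number analysis
#'
#' Defines the simulation scenario used to answer "how many boli per
#' condition are needed to detect an individual BRS change?". True responder
#' effects are drawn from Normal(\code{effect_mean}, \code{effect_sd}^2) --
#' default 6 +/- 3 ms/mmHg, the empirical distribution of individual
#' normoxia-hypoxia BRS differences -- and per-bolus values vary with SD
#' \code{bolus_sd} (default: derived from the published per-subject SEM x
#' sqrt(n), see \code{\link{derive_bolus_sd_from_table}}).
#'
#' @param effect_mean mean true individual effect, ms/mmHg.
#' @param effect_sd SD of true effects across responders, ms/mmHg.
#' @param bolus_sd within-condition per-bolus SD, ms/mmHg (> 0).
#' @param n_grid candidate numbers of boli per condition (each >= 2).
#' @param n_sim simulated individuals per grid point and class.
#' @param alpha significance level of the per-individual test.
#' @param target_sensitivity sensitivity the plan should reach, in (0, 1).
#' @param method \code{"ttest_power"}: sensitivity = fraction of responders
#'   with Welch p < alpha. \code{"roc_mean_classifier"}: the observed mean
#'   difference is used as a score to discriminate responders from
#'   non-responders; sensitivity is read at the Youden-optimal ROC point and
#'   the AUC is also reported.
#' @param pooled use the pooled-variance test in the ttest_power method.
#'   Welch (the default elsewhere) is marginally conservative at small n;
#'   the pooled variant is the one whose power has the exact noncentral-t
#'   closed form (\code{\link{closed_form_power}}).
#' @export
plan_spec <- function(effect_mean = 6, effect_sd = 3,
                      bolus_sd = derive_bolus_sd_from_table(),
                      n_grid = c(2, 3, 4, 5, 7, 10, 15, 20), n_sim = 500,
                      alpha = 0.05, target_sensitivity = 0.8,
                      method = c("ttest_power", "roc_mean_classifier"),
                      pooled = FALSE) {
  method <- match.arg(method)
  if (bolus_sd <= 0) stop_("bolus_sd must be positive")
  if (effect_sd < 0) stop_("effect_sd must be >= 0")
  if (any(n_grid < 2)) stop_("every n_grid entry must be >= 2")
  if (target_sensitivity <= 0 || target_sensitivity >= 1)
    stop_("target_sensitivity must lie in (0, 1)")
  structure(list(effect_mean = effect_mean, effect_sd = effect_sd,
                 bolus_sd = bolus_sd, n_grid = sort(unique(as.integer(n_grid))),
                 n_sim = as.integer(n_sim), alpha = alpha,
                 target_sensitivity = target_sensitivity, method = method,
                 pooled = pooled),
            class = "plan_spec")
}

#' Per-bolus SD implied by a published summary table
#'
#' Each published per-subject row reports mean +/- SEM over n boli, so the
#' per-bolus SD that row implies is SEM x sqrt(n). The planner's default
#' noise level is the median of these SDs over all subject-condition rows of
#' the BRS reference table (both conditions).
#'
#' @param sem vector of SEMs; defaults to the packaged BRS table.
#' @param n vector of bolus counts, aligned with \code{sem}.
#' @return Median per-bolus SD, ms/mmHg.
#' @export
derive_bolus_sd_from_table <- function(sem = NULL, n = NULL) {
  if (is.null(sem)) {
    tab <- reference_summaries("brs")
    sem <- c(tab$brs_normoxia_sem, tab$brs_hypoxia_sem)
    n <- c(tab$brs_normoxia_n, tab$brs_hypoxia_n)
  }
  if (length(sem) < 1) stop_("at least one row required")
  if (any(n <= 0)) stop_("bolus counts must be positive")
  if (any(sem < 0)) stop_("SEMs must be >= 0")
  median(sem * sqrt(n))
}

#' Closed-form power of the unpaired t test
#'
#' Two-sided, two-sample t power via the noncentral t distribution with
#' noncentrality \code{delta / (bolus_sd * sqrt(2 / n_per_arm))} and
#' \code{2 * n_per_arm - 2} degrees of freedom.
#'
#' @param delta true mean difference.
#' @param bolus_sd per-observation SD (common to both arms).
#' @param n_per_arm observations per arm (>= 2).
#' @param alpha two-sided significance level.
#' @return Power in [0, 1] (equals alpha when \code{delta = 0}).
#' @export
closed_form_power <- function(delta, bolus_sd, n_per_arm, alpha = 0.05) {
  stopifnot(n_per_arm >= 2, bolus_sd > 0)
  df <- 2 * n_per_arm - 2
  ncp <- delta / (bolus_sd * sqrt(2 / n_per_arm))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}

# Unpaired-test p values for column-paired matrices (one simulated
# individual per column), vectorized over individuals.
welch_p_cols <- function(x, y, pooled = FALSE) {
  nx <- nrow(x); ny <- nrow(y)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- (colSums(x^2) - nx * mx^2) / (nx - 1)
  vy <- (colSums(y^2) - ny * my^2) / (ny - 1)
  if (pooled) {
    s2p <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- s2p * (1 / nx + 1 / ny)
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / sqrt(se2)
  2 * pt(-abs(t), df)
}

#' Sensitivity of the N-of-1 decision versus number of boli
#'
#' For each candidate repetition count n, simulates \code{n_sim} responder
#' individuals (true difference drawn from the effect distribution) and
#' \code{n_sim} non-responders (true difference 0), draws n noisy boli per
#' condition for each, and measures how often the per-individual decision
#' detects the responders. Method \code{"ttest_power"} counts Welch
#' p < alpha among responders; method \code{"roc_mean_classifier"} scores
#' each individual by the observed mean difference and reads sensitivity at
#' the Youden-optimal threshold of the responder/non-responder ROC curve
#' (AUC also reported). Deterministic given (spec, seed).
#'
#' @param spec a \code{\link{plan_spec}}.
#' @param seed integer seed.
#' @return A \code{plan_result} list: \code{curve} (data.frame with
#'   \code{n_boli}, \code{sensitivity}, \code{mc_se}, and \code{auc} for the
#'   ROC method), \code{minimal_n} (smallest grid entry reaching the target,
#'   NA if none), plus the spec.
#' @export
sensitivity_curve <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "plan_spec"))
  rows <- lapply(spec$n_grid, function(n) {
    set.seed(child_seed(seed, n))
    eff <- rnorm(spec$n_sim, spec$effect_mean, spec$effect_sd)
    resp_a <- matrix(rnorm(n * spec$n_sim, 0, spec$bolus_sd), n)
    resp_b <- matrix(rnorm(n * spec$n_sim, rep(eff, each = n),
                           spec$bolus_sd), n)
    null_a <- matrix(rnorm(n * spec$n_sim, 0, spec$bolus_sd), n)
    null_b <- matrix(rnorm(n * spec$n_sim, 0, spec$bolus_sd), n)
    if (spec$method == "ttest_power") {
      p <- welch_p_cols(resp_b, resp_a, pooled = spec$pooled)
      sens <- mean(p < spec$alpha)
      data.frame(n_boli = n, sensitivity = sens,
                 mc_se = sqrt(sens * (1 - sens) / spec$n_sim),
                 auc = NA_real_)
    } else {
      score <- c(colMeans(resp_b) - colMeans(resp_a),
                 colMeans(null_b) - colMeans(null_a))
      truth <- rep(c(1L, 0L), each = spec$n_sim)
      roc <- pROC::roc(truth, score, direction = "<", quiet = TRUE)
      best <- pROC::coords(roc, "best", best.method = "youden",
                           ret = c("sensitivity", "specificity"),
                           transpose = FALSE)
      sens <- max(best$sensitivity)   # ties on Youden: keep highest sensitivity
      data.frame(n_boli = n, sensitivity = sens,
                 mc_se = sqrt(sens * (1 - sens) / spec$n_sim),
                 auc = as.numeric(pROC::auc(roc)))
    }
  })
  curve <- do.call(rbind, rows)
  hit <- which(curve$sensitivity >= spec$target_sensitivity)
  structure(list(curve = curve,
                 minimal_n = if (length(hit)) curve$n_boli[min(hit)]
                             else NA_integer_,
                 spec = spec, seed = seed),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> method %s, effect %g +/- %g, bolus SD %.2f\n",
              x$spec$method, x$spec$effect_mean, x$spec$effect_sd,
              x$spec$bolus_sd))
  print.data.frame(x$curve, row.names = FALSE, digits = 3)
  cat(if (is.na(x$minimal_n))
        sprintf("no grid entry reaches sensitivity %.2f\n",
                x$spec$target_sensitivity)
      else sprintf("minimal n reaching sensitivity %.2f: %d boli\n",
                   x$spec$target_sensitivity, x$minimal_n))
  invisible(x)
}
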