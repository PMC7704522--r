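#' Hypoxic respiratory chemoreflex response
#'
#' Minute-ventilation change per unit hypoxic desaturation,
#' \code{(ve_hyp - ve_norm) / delta_spo2}. By default the ratio is scaled by
#' 100 (\code{scale100 = TRUE}): the published per-subject table treats the
#' desaturation as a fraction, and recomputing its chemoreflex column from
#' its own ventilation and delta-SpO2 cells requires this x100 convention
#' even though the column is labelled (l/min)/\%. Set \code{scale100 =
#' FALSE} for the plain ratio.
#'
#' @param ve_norm,ve_hyp minute ventilation in normoxia / hypoxia, l/min.
#' @param delta_spo2 saturation drop (normoxia minus hypoxia), percent;
#'   must be positive for a valid hypoxia exposure.
#' @param scale100 apply the x100 table convention.
#' @return Chemoreflex response (vectorized over subjects).
#' @export
#' @examples
#' chemoreflex_response(13.66, 12.50, 15.29)  # approx -7.59
chemoreflex_response <- function(ve_norm, ve_hyp, delta_spo2,
                                 scale100 = TRUE) {
  if (any(delta_spo2 <= 0))
    stop_("delta_spo2 must be positive (got %g); hypoxia must desaturate",
          min(delta_spo2))
  (if (scale100) 100 else 1) * (ve_hyp - ve_norm) / delta_spo2
}

#' Cohort mean chemoreflex response
#'
#' @param responses per-subject chemoreflex responses.
#' @return A list: \code{mean}, \code{sem}, \code{n}.
#' @export
cohort_chemoreflex_mean <- function(responses) {
  if (length(responses) < 1) stop_("no rows")
  list(mean = mean(responses), sem = sem(responses), n = length(responses))
}

#' Per-subject respiratory summary with chemoreflex response
#'
#' Computes each subject's chemoreflex response from a respiratory summary
#' table (layout of \code{reference_summaries("respiratory")}) and checks
#' the internal consistency of the ventilation columns: minute ventilation
#' should equal respiratory rate times tidal volume within a stated
#' tolerance (device-derived summaries need not multiply exactly).
#'
#' @param table respiratory summary data.frame; defaults to the packaged
#'   reference table.
#' @param consistency_tol relative tolerance for ve vs rate x tidal volume;
#'   rows outside it are flagged in the \code{ve_consistent} column.
#' @return The table with \code{chemoreflex_response} and
#'   \code{ve_consistent} columns appended.
#' @export
respiratory_summary <- function(table = reference_summaries("respiratory"),
                                consistency_tol = 0.2) {
  table$chemoreflex_response <- chemoreflex_response(
    table$ve_normoxia, table$ve_hypoxia, table$delta_spo2)
  rel_err <- function(ve, rr, vt) abs(ve - rr * vt) / ve
  table$ve_consistent <-
    rel_err(table$ve_normoxia, table$rr_normoxia, table$vt_normoxia) <=
      consistency_tol &
    rel_err(table$ve_hypoxia, table$rr_hypoxia, table$vt_hypoxia) <=
      consistency_tol
  table
}
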