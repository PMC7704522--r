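#' Published per-subject reference summaries
#'
#' Per-subject summary statistics from a published crossover study of nine
#' healthy young men tested under normoxia and normocapnic hypoxia (SpO2
#' target 80\%), with up to 20 phenylephrine boli per condition. Three tables
#' are shipped as plain-text fixtures:
#'
#' \describe{
#'   \item{\code{"brs"}}{per-subject cardiovagal BRS: mean, SEM and number of
#'     accepted boli per condition, plus the printed p and t of the
#'     per-subject unpaired test.}
#'   \item{\code{"pressor"}}{per-subject phenylephrine pressor response
#'     (delta-SBP, mmHg) in the same layout.}
#'   \item{\code{"respiratory"}}{per-subject respiratory rate, tidal volume and
#'     minute ventilation (mean and SEM per condition), the hypoxic
#'     desaturation delta-SpO2 (\%), and the printed chemoreflex response.}
#' }
#'
#' These summaries parameterize the default simulated cohort
#' (\code{\link{reference_cohort_spec}}) and serve as direct inputs for the
#' summary-level inference functions.
#'
#' @param table one of \code{"brs"}, \code{"pressor"}, \code{"respiratory"}.
#' @return A data.frame, one row per subject.
#' @export
#' @examples
#' head(reference_summaries("brs"))
reference_summaries <- function(table = c("brs", "pressor", "respiratory")) {
  table <- match.arg(table)
  file <- c(brs = "brs_by_subject.csv",
            pressor = "pressor_by_subject.csv",
            respiratory = "respiratory_by_subject.csv")[[table]]
  path <- system.file("extdata", file, package = "baroN1", mustWork = TRUE)
  read.csv(path, colClasses = c(subject = "character"))
}
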