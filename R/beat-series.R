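#' Beat-indexed physiological record
#'
#' A \code{beat_series} is a data.frame with one row per heartbeat and columns
#' \code{beat_index}, \code{time_s}, \code{rri_ms} (the RR interval ending at
#' this beat, so \code{time_s[k] - time_s[k-1] == rri_ms[k]/1000}) and
#' \code{sbp_mmhg}, plus \code{subject_id} and \code{condition} attributes.
#'
#' @param df data.frame with the four columns above.
#' @param subject_id subject identifier.
#' @param condition condition label.
#' @param validate check physiological invariants (strictly increasing time,
#'   RR intervals within 300-2000 ms, SBP within 50-300 mmHg, >= 12 beats)?
#' @return A \code{beat_series} object.
#' @export
beat_series <- function(df, subject_id = "unknown", condition = "unknown",
                        validate = TRUE) {
  out <- new_beat_series(df, subject_id, condition)
  if (validate) validate_beat_series(out)
  out
}

new_beat_series <- function(df, subject_id, condition) {
  need <- c("beat_index", "time_s", "rri_ms", "sbp_mmhg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("beat series lacks columns: %s",
                          paste(miss, collapse = ", "))
  structure(df[need], class = c("beat_series", "data.frame"),
            subject_id = as.character(subject_id),
            condition = as.character(condition))
}

validate_beat_series <- function(b) {
  if (nrow(b) < 12) stop_("beat series has %d beats; at least 12 required",
                          nrow(b))
  dt <- diff(b$time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop_("beat times not strictly increasing at beat %d (t = %g s)",
          bad, b$time_s[bad])
  }
  bad_rri <- which(b$rri_ms < 300 | b$rri_ms > 2000)
  if (length(bad_rri))
    stop_("RR interval outside 300-2000 ms at beat(s) %s",
          paste(head(bad_rri, 5), collapse = ", "))
  bad_sbp <- which(b$sbp_mmhg < 50 | b$sbp_mmhg > 300)
  if (length(bad_sbp))
    stop_("SBP outside 50-300 mmHg at beat(s) %s",
          paste(head(bad_sbp, 5), collapse = ", "))
  invisible(b)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> subject %s, %s: %d beats over %.1f s\n",
              attr(x, "subject_id"), attr(x, "condition"), nrow(x),
              diff(range(x$time_s))))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more beats\n", nrow(x) - 5L))
  invisible(x)
}
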