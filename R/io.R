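# CSV dialects and configuration.
#
# All tables are plain UTF-8 CSV with dot decimals and a mandatory header
# row. Lines starting with '#' are metadata comments (package version,
# config hash) and are skipped on read. Numeric values are written with 17
# significant digits so a write -> read round trip reproduces doubles
# exactly.

fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

std_comments <- function(config = NULL) {
  c(sprintf("baroN1 %s", as.character(packageVersion("baroN1"))),
    if (!is.null(config)) sprintf("config_hash %s", config_hash(config)))
}

#' Write / read a beat series as CSV
#'
#' Columns \code{beat_index}, \code{time_s}, \code{rri_ms},
#' \code{sbp_mmhg}; subject and condition are stored in comment lines.
#' Reading validates the physiological invariants (strictly increasing
#' time, RR intervals within 300-2000 ms, SBP within 50-300 mmHg) and
#' reports offending beats.
#'
#' @param beats a \code{\link{beat_series}}.
#' @param path file path.
#' @param config optional pipeline config recorded in the header.
#' @return \code{write_beats}: the path, invisibly. \code{read_beats}: a
#'   validated \code{beat_series}.
#' @export
write_beats <- function(beats, path, config = NULL) {
  write_csv_commented(as.data.frame(beats), path, c(
    std_comments(config),
    sprintf("subject_id %s", attr(beats, "subject_id")),
    sprintf("condition %s", attr(beats, "condition"))))
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  meta <- read_comment_meta(path)
  df <- read_checked_csv(path, c("beat_index", "time_s", "rri_ms",
                                 "sbp_mmhg"))
  beat_series(df, subject_id = meta["subject_id"] %|% "unknown",
              condition = meta["condition"] %|% "unknown")
}

`%|%` <- function(x, y) if (is.na(x) || is.null(x)) y else x

read_comment_meta <- function(path) {
  lines <- readLines(path, n = 20L, encoding = "UTF-8")
  lines <- lines[startsWith(lines, "#")]
  out <- c(subject_id = NA_character_, condition = NA_character_)
  for (l in lines) {
    parts <- strsplit(sub("^#\\s*", "", l), "\\s+")[[1]]
    if (length(parts) >= 2 && parts[1] %in% names(out))
      out[parts[1]] <- parts[2]
  }
  out
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  raw <- readLines(path, encoding = "UTF-8")
  n_comment <- sum(cumprod(startsWith(raw, "#")))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  for (col in required) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop_("%s: malformed value in column %s at line(s) %s", path, col,
            paste(head(bad + n_comment + 1L, 5), collapse = ", "))
  }
  df
}

#' Write / read bolus events as CSV
#'
#' Columns \code{bolus_index}, \code{time_s}, \code{dose_ug},
#' \code{condition} (plus \code{subject} when present).
#'
#' @param events bolus events data.frame.
#' @param path file path.
#' @param config optional pipeline config recorded in the header.
#' @export
write_events <- function(events, path, config = NULL) {
  write_csv_commented(as.data.frame(events), path, std_comments(config))
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_checked_csv(path, c("bolus_index", "time_s"))
  structure(df, class = c("bolus_events", "data.frame"))
}

#' Write / read a per-bolus responses table as CSV
#'
#' @param responses a \code{bolus_responses} data.frame.
#' @param path file path.
#' @param config optional pipeline config recorded in the header.
#' @export
write_responses <- function(responses, path, config = NULL) {
  write_csv_commented(as.data.frame(responses), path, std_comments(config))
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = c(subject = "character"))
  structure(df, class = c("bolus_responses", "data.frame"))
}

#' Pipeline configuration
#'
#' Assembles and validates the full configuration of
#' \code{\link{run_pipeline}}: extraction settings, statistics settings,
#' bolus schedule, plan specification and master seed. Unknown keys are
#' rejected; every numeric setting is bounds-checked by the constructor it
#' feeds.
#'
#' @param seed master seed.
#' @param extraction named list overriding \code{\link{extraction_settings}}
#'   defaults.
#' @param statistics named list: \code{alpha}, \code{pooled},
#'   \code{p_adjust}.
#' @param schedule named list overriding \code{\link{bolus_schedule}}
#'   defaults.
#' @param plan named list overriding \code{\link{plan_spec}} defaults.
#' @param cohort \code{"reference"} (the default nine-subject cohort) or a
#'   list of per-subject parameter lists with \code{subject_id},
#'   \code{normoxia} and \code{hypoxia} sublists of
#'   \code{\link{condition_params}} fields.
#' @return A validated \code{pipeline_config} object.
#' @export
pipeline_config <- function(seed = 1L, extraction = list(),
                            statistics = list(), schedule = list(),
                            plan = list(), cohort = "reference") {
  check_keys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown))
      stop_("unknown %s key(s): %s", where, paste(unknown, collapse = ", "))
  }
  check_keys(extraction, names(formals(extraction_settings)), "extraction")
  check_keys(statistics, c("alpha", "pooled", "p_adjust"), "statistics")
  check_keys(schedule, names(formals(bolus_schedule)), "schedule")
  check_keys(plan, names(formals(plan_spec)), "plan")
  stats_defaults <- list(alpha = 0.05, pooled = FALSE, p_adjust = "none")
  statistics <- modifyList(stats_defaults, statistics)
  if (statistics$alpha <= 0 || statistics$alpha >= 1)
    stop_("alpha must lie in (0, 1)")
  cfg <- structure(list(seed = as.integer(seed), extraction = extraction,
                        statistics = statistics, schedule = schedule,
                        plan = plan, cohort = cohort),
                   class = "pipeline_config")
  # Force constructor-level validation now, not at run time.
  do.call(extraction_settings, extraction)
  do.call(bolus_schedule, schedule)
  do.call(plan_spec, plan)
  if (!identical(cohort, "reference")) cohort_spec_from_config(cohort)
  cfg
}

cohort_spec_from_config <- function(cohort) {
  if (identical(cohort, "reference")) return(reference_cohort_spec())
  lapply(cohort, function(s) {
    stopifnot(!is.null(s$subject_id))
    subject_spec(s$subject_id,
                 do.call(condition_params,
                         c(list(label = "normoxia"), s$normoxia)),
                 do.call(condition_params,
                         c(list(label = "hypoxia"), s$hypoxia)))
  })
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization round-trips: \code{read_config(write_config(cfg))} is
#' identical to \code{cfg}. Unknown keys in the file are rejected.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Stable hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; platform-independent, used to
#' stamp every output table so results are traceable to their settings.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
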