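#' Construct a sepsis cohort object
#'
#' A `sepsis_cohort` bundles the three long-format tables the pipeline
#' consumes:
#'
#' * `events`: one row per raw measurement, columns `event_id` (integer,
#'   unique), `admission_id`, `feature`, `time_hours` (hours since
#'   admission, non-negative), `value` (numeric, feature units).
#' * `meta`: one row per admission, columns `admission_id`, `age` (years),
#'   `weight` (kg), `stay_hours` (integer stay length), `flag_chronic_renal`,
#'   `flag_chronic_liver`, `flag_pneumonia` (logicals from ICD-9-derived
#'   chronic-condition coding), `outcome_label` (logical; developed septic
#'   shock during the admission — the generator's intent for synthetic data,
#'   or the labeler's verdict for real extracts).
#' * `infections`: zero or more rows per admission, columns `admission_id`,
#'   `start_hour`, `end_hour` — half-open hour intervals `[start, end)`
#'   during which an infection was suspected. Suspicion is an input, not a
#'   computed quantity: real-data adapters populate it upstream.
#'
#' @param events,meta,infections Data frames as described above.
#' @return An object of class `sepsis_cohort`.
#' @export
sepsis_cohort <- function(events, meta, infections = NULL) {
  if (is.null(infections)) {
    infections <- data.frame(admission_id = character(), start_hour = numeric(),
                             end_hour = numeric(), stringsAsFactors = FALSE)
  }
  obj <- structure(list(events = events, meta = meta, infections = infections),
                   class = "sepsis_cohort")
  validate_cohort(obj)
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "sepsis_cohort"))
  ev_cols <- c("event_id", "admission_id", "feature", "time_hours", "value")
  me_cols <- c("admission_id", "age", "weight", "stay_hours",
               "flag_chronic_renal", "flag_chronic_liver", "flag_pneumonia",
               "outcome_label")
  miss <- setdiff(ev_cols, names(x$events))
  if (length(miss)) stop("events table missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(me_cols, names(x$meta))
  if (length(miss)) stop("meta table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$meta$admission_id)) stop("duplicated admission_id in meta")
  if (nrow(x$events)) {
    if (anyDuplicated(x$events$event_id)) stop("duplicated event_id in events")
    if (any(x$events$time_hours < 0)) stop("negative event times in events table")
    unknown <- setdiff(unique(x$events$admission_id), x$meta$admission_id)
    if (length(unknown)) {
      stop("events reference admission(s) absent from meta: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  if (any(x$meta$age <= 0)) stop("non-positive age in meta")
  if (any(x$meta$weight <= 0)) stop("non-positive weight in meta")
  if (nrow(x$infections)) {
    if (any(x$infections$end_hour <= x$infections$start_hour)) {
      stop("infection intervals must satisfy start_hour < end_hour")
    }
  }
  invisible(x)
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  n <- nrow(x$meta)
  pos <- sum(x$meta$outcome_label)
  cat(sprintf("<sepsis_cohort> %d admissions (%d septic-shock positive), %d events\n",
              n, pos, nrow(x$events)))
  cat(sprintf("  stay length: %d-%d h; features: %d\n",
              min(x$meta$stay_hours), max(x$meta$stay_hours),
              length(unique(x$events$feature))))
  invisible(x)
}

#' Write / read a cohort as CSV files
#'
#' Serializes the three component tables to `events.csv`, `meta.csv` and
#' `infections.csv` inside `dir` (UTF-8, '.' decimal separator, header row).
#' This is the package's canonical on-disk event dialect; column
#' dictionaries are in [sepsis_cohort()].
#'
#' @param cohort A `sepsis_cohort`.
#' @param dir Directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   validated `sepsis_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$infections, file.path(dir, "infections.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  read1 <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  meta <- read1("meta.csv")
  for (fl in c("flag_chronic_renal", "flag_chronic_liver", "flag_pneumonia", "outcome_label")) {
    meta[[fl]] <- as.logical(meta[[fl]])
  }
  sepsis_cohort(read1("events.csv"), meta, read1("infections.csv"))
}

#' Filter a cohort by minimum admission age
#'
#' Removes admissions younger than `min_age` years at admission time (the
#' SIRS-based sepsis definitions differ for children, so pediatric
#' admissions are excluded before any downstream step). The retained set is
#' exactly `age >= min_age`.
#'
#' @param cohort A `sepsis_cohort`.
#' @param min_age Minimum age in years retained (default 15).
#' @return The filtered `sepsis_cohort`, with an attribute `n_removed`
#'   recording how many admissions were dropped.
#' @export
filter_age <- function(cohort, min_age = 15) {
  validate_cohort(cohort)
  if (any(is.na(cohort$meta$age))) {
    bad <- cohort$meta$admission_id[is.na(cohort$meta$age)]
    stop("admission(s) without age: ", paste(bad, collapse = ", "))
  }
  keep <- cohort$meta$age >= min_age
  ids <- cohort$meta$admission_id[keep]
  out <- structure(list(
    events = cohort$events[cohort$events$admission_id %in% ids, , drop = FALSE],
    meta = cohort$meta[keep, , drop = FALSE],
    infections = cohort$infections[cohort$infections$admission_id %in% ids, , drop = FALSE]
  ), class = "sepsis_cohort")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Is an infection suspected at each hour of an admission?
#'
#' @param hours Integer vector of hour indices (0-based, since admission).
#' @param infections The cohort `infections` table.
#' @param admission_id Admission to query.
#' @return Logical vector: hour h lies in some half-open interval
#'   `[start_hour, end_hour)` for this admission.
#' @export
infection_suspected_at <- function(hours, infections, admission_id) {
  iv <- infections[infections$admission_id == admission_id, , drop = FALSE]
  if (!nrow(iv)) return(rep(FALSE, length(hours)))
  out <- rep(FALSE, length(hours))
  for (i in seq_len(nrow(iv))) {
    out <- out | (hours >= iv$start_hour[i] & hours < iv$end_hour[i])
  }
  out
}
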