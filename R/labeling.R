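#' Hourly sepsis-state labeling (Sepsis-2 / SIRS criteria)
#'
#' These functions implement the operational, SIRS-based definitions of
#' sepsis, severe sepsis and septic shock used by TREWScore-style early
#' warning studies, applied on an hourly grid:
#'
#' * **SIRS criteria** (each counts at most once): body temperature
#'   outside 36-38 degC; heart rate >90/min; respiratory rate >20/min or
#'   PaCO2 <32 mmHg; white-cell count <4,000 or >12,000 per uL.
#' * **Sepsis**: at least two SIRS criteria while an infection is suspected.
#' * **Severe sepsis**: sepsis plus any sepsis-related organ dysfunction.
#' * **Septic shock**: severe sepsis plus hypotension (systolic blood
#'   pressure <90 mmHg) despite adequate fluid resuscitation.
#' * **Adequate fluid resuscitation**: >=20 mL/kg given over the trailing
#'   24 h, or a total fluid replacement >=1200 mL.
#'
#' All comparisons are exactly as printed above: ">" and "<" strict, ">="
#' inclusive (e.g. SBP exactly 90 is *not* hypotension). Criteria are
#' evaluated on imputed physical-unit values; standardization is for the
#' model only.
#'
#' `obs` is a data.frame (or list of equal-length vectors) with one row per
#' hour and the columns named below; all functions are vectorized over rows.
#'
#' @param obs Observations with columns `temperature` (degC), `heart_rate`
#'   (beats/min), `respiratory_rate` (breaths/min), `paco2` (mmHg), `wbc`
#'   (cells/uL); `organ_dysfunction` and `label_hour` additionally need
#'   `sbp` (mmHg), `lactate` (mmol/L), `urine_output_2h_per_kg` (mL/kg over
#'   the trailing 2 h), `creatinine` (mg/dL), `bilirubin` (mg/dL),
#'   `platelets` (count/uL), `inr`, `pao2_fio2` (mmHg), `fluids_24h` (mL
#'   over the trailing 24 h) and `fluids_total` (mL since admission).
#'   Values must be imputed (no `NA`).
#' @return `count_sirs`: integer vector in 0..4.
#' @export
count_sirs <- function(obs) {
  stop_if_na(obs, c("temperature", "heart_rate", "respiratory_rate", "paco2", "wbc"))
  temp <- (obs$temperature < 36) | (obs$temperature > 38)
  hr <- obs$heart_rate > 90
  resp <- (obs$respiratory_rate > 20) | (obs$paco2 < 32)
  wbc <- (obs$wbc < 4000) | (obs$wbc > 12000)
  as.integer(temp) + as.integer(hr) + as.integer(resp) + as.integer(wbc)
}

#' @rdname count_sirs
#' @param infection_suspected Logical vector: infection suspected this hour.
#' @return `is_sepsis`: logical vector, `count_sirs(obs) >= 2` and infection
#'   suspected.
#' @export
is_sepsis <- function(obs, infection_suspected) {
  count_sirs(obs) >= 2L & infection_suspected
}

#' @rdname count_sirs
#' @param fluids_24h Fluid replacement (mL) over the trailing 24 hours.
#' @param fluids_total Cumulative fluid replacement (mL) since admission.
#' @param weight Patient weight (kg), positive.
#' @return `fluid_adequate`: logical, `fluids_24h / weight >= 20` or
#'   `fluids_total >= 1200`.
#' @export
fluid_adequate <- function(fluids_24h, fluids_total, weight) {
  if (any(weight <= 0, na.rm = TRUE) || any(is.na(weight))) {
    stop("weight must be positive and non-missing")
  }
  (fluids_24h / weight >= 20) | (fluids_total >= 1200)
}

#' @rdname count_sirs
#' @param meta A one-row slice of the cohort `meta` table (needs
#'   `flag_chronic_renal`, `flag_chronic_liver`, `flag_pneumonia`).
#' @param fluids_adequate Logical vector from [fluid_adequate()]; gates the
#'   oliguria criterion ("despite adequate fluid resuscitation").
#' @return `organ_dysfunction`: logical vector; any of the nine
#'   sub-criteria holds, with the ICD-9 chronic-condition exclusions
#'   (chronic renal disease suppresses the creatinine criterion, chronic
#'   liver disease the bilirubin criterion, and pneumonia selects which
#'   PaO2/FiO2 cutoff applies).
#' @export
organ_dysfunction <- function(obs, meta, fluids_adequate) {
  stop_if_na(obs, c("sbp", "lactate", "urine_output_2h_per_kg", "creatinine",
                    "bilirubin", "platelets", "inr", "pao2_fio2"))
  (obs$sbp < 90) |
    (obs$lactate > 2.0) |
    (obs$urine_output_2h_per_kg < 0.5 & fluids_adequate) |
    (obs$creatinine > 2.0 & !meta$flag_chronic_renal) |
    (obs$bilirubin > 2.0 & !meta$flag_chronic_liver) |
    (obs$platelets < 100000) |
    (obs$inr > 1.5) |
    (obs$pao2_fio2 < 200 & meta$flag_pneumonia) |
    (obs$pao2_fio2 < 250 & !meta$flag_pneumonia)
}

#' @rdname count_sirs
#' @return `label_hour`: ordered factor with levels
#'   `negative < sepsis < severe_sepsis < septic_shock`; the highest
#'   applicable state per hour.
#' @export
label_hour <- function(obs, meta, infection_suspected) {
  fa <- fluid_adequate(obs$fluids_24h, obs$fluids_total, meta$weight)
  sep <- is_sepsis(obs, infection_suspected)
  severe <- sep & organ_dysfunction(obs, meta, fluids_adequate = fa)
  shock <- severe & (obs$sbp < 90) & fa
  state <- ifelse(shock, "septic_shock",
                  ifelse(severe, "severe_sepsis",
                         ifelse(sep, "sepsis", "negative")))
  sepsis_state_factor(state)
}

#' @export
#' @rdname count_sirs
sepsis_state_levels <- function() {
  c("negative", "sepsis", "severe_sepsis", "septic_shock")
}

sepsis_state_factor <- function(x) {
  factor(x, levels = sepsis_state_levels(), ordered = TRUE)
}

stop_if_na <- function(obs, cols) {
  for (cl in cols) {
    v <- obs[[cl]]
    if (is.null(v)) stop("observations are missing column '", cl, "'")
    if (anyNA(v)) stop("observations contain NA in '", cl, "' (impute first)")
  }
  invisible(TRUE)
}

#' Label every hour of one admission
#'
#' Applies [label_hour()] to a fully-imputed hourly observation table for a
#' single admission and locates septic-shock onset (the first hour labeled
#' `septic_shock`, if any).
#'
#' @param obs Hourly observation data.frame (one row per hour, hour 0 =
#'   admission) with all columns required by [label_hour()] plus a logical
#'   `infection_suspected` column.
#' @param meta One-row meta slice for the admission (see [sepsis_cohort()]).
#' @return A `sepsis_states` object: list with `admission_id`, `states`
#'   (ordered factor, one per hour) and `onset_hour` (0-based hour index or
#'   `NA` if septic shock never occurs).
#' @export
label_admission <- function(obs, meta) {
  if (!nrow(obs)) stop("empty hourly grid for admission ", meta$admission_id)
  states <- label_hour(obs, meta, obs$infection_suspected)
  shock_hours <- which(states == "septic_shock")
  structure(list(
    admission_id = meta$admission_id,
    states = states,
    onset_hour = if (length(shock_hours)) shock_hours[1] - 1L else NA_integer_
  ), class = "sepsis_states")
}

#' @export
print.sepsis_states <- function(x, ...) {
  cat(sprintf("<sepsis_states> %s: %d h, max state %s, onset %s\n",
              x$admission_id, length(x$states), as.character(max(x$states)),
              ifelse(is.na(x$onset_hour), "none", x$onset_hour)))
  invisible(x)
}

#' Label a whole cohort hour-by-hour
#'
#' Runs the labeling front half of the pipeline on raw events: clinical
#' range outlier removal, hourly binning, zero-order-hold imputation with a
#' reference-normal fallback for never-observed criteria features,
#' trailing-window fluid/urine derivations from raw event times, then
#' [label_admission()] per admission. Labeling always operates on physical
#' units.
#'
#' @param cohort A `sepsis_cohort`.
#' @param ranges Feature table (default [default_feature_table()]).
#' @return A list with `states` (data.frame `admission_id`, `hour`,
#'   `state`), `onsets` (data.frame `admission_id`, `onset_hour` (NA if
#'   none), `shock` logical) and `per_admission` (named list of
#'   `sepsis_states`).
#' @export
label_cohort <- function(cohort, ranges = default_feature_table()) {
  validate_cohort(cohort)
  ev <- remove_outliers(cohort$events, ranges)
  per <- vector("list", nrow(cohort$meta))
  names(per) <- cohort$meta$admission_id
  for (i in seq_len(nrow(cohort$meta))) {
    meta_i <- cohort$meta[i, , drop = FALSE]
    obs <- admission_observations(ev, meta_i, cohort$infections, ranges)
    per[[i]] <- label_admission(obs, meta_i)
  }
  states <- do.call(rbind, lapply(per, function(s) {
    data.frame(admission_id = s$admission_id,
               hour = seq_along(s$states) - 1L,
               state = as.character(s$states),
               stringsAsFactors = FALSE)
  }))
  rownames(states) <- NULL
  onsets <- data.frame(
    admission_id = vapply(per, function(s) as.character(s$admission_id), ""),
    onset_hour = vapply(per, function(s) as.integer(s$onset_hour), 1L),
    stringsAsFactors = FALSE
  )
  onsets$shock <- !is.na(onsets$onset_hour)
  rownames(onsets) <- NULL
  list(states = states, onsets = onsets, per_admission = per)
}

# Build the fully-imputed hourly observation table the labeler needs for
# one admission: bin criteria features to the nearest whole hour, carry the
# last observation forward, fall back to the feature's reference normal
# value before any observation exists, and attach trailing-window
# fluid/urine quantities computed from raw (pre-binning) event times.
admission_observations <- function(events, meta, infections, ranges) {
  aid <- meta$admission_id
  stay <- meta$stay_hours
  hours <- seq_len(stay) - 1L
  ev <- events[events$admission_id == aid, , drop = FALSE]
  feats <- criteria_features()
  grid <- bin_hourly(ev[ev$feature %in% feats, , drop = FALSE],
                     stay_length = stay, features = feats,
                     admission_id = aid)
  grid <- impute_zoh(grid)
  normals <- ranges$normal[match(feats, ranges$feature)]
  vals <- grid$values
  for (j in seq_along(feats)) {
    vals[is.na(vals[, j]), j] <- normals[j]
  }
  obs <- as.data.frame(vals)
  names(obs) <- feats
  tw <- trailing_windows(ev, hours = hours, weight = meta$weight)
  obs$urine_output_2h_per_kg <- tw$urine_output_2h_per_kg
  obs$fluids_24h <- tw$fluids_24h
  obs$fluids_total <- tw$fluids_total
  obs$infection_suspected <- infection_suspected_at(hours, infections, aid)
  obs
}

#' Write hourly states and onset summaries as CSV
#'
#' @param labels Result of [label_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `states.csv` (admission_id, hour,
#'   state) and `onsets.csv` (admission_id, onset_hour, shock).
#' @export
write_labels <- function(labels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(labels$states, file.path(dir, "states.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(labels$onsets, file.path(dir, "onsets.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
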