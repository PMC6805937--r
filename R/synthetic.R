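#' Synthetic ICU cohort configuration
#'
#' Controls the seeded generator of synthetic ICU admissions used to
#' exercise the labeling, feature and model pipeline without credentialed
#' EHR data. Admissions destined to develop septic shock are drawn by
#' count (`round(shock_fraction * n_admissions)`, exact prevalence, not
#' Bernoulli) and their trajectories are built compositionally so that
#' every labeling sub-rule is reachable: first at least two SIRS criteria
#' ramp up inside an infection-suspicion interval, then an
#' organ-dysfunction criterion (rising lactate), then fluid boluses cross
#' the resuscitation-adequacy rule, and only then does systolic pressure
#' fall below 90 mmHg — pinning septic-shock onset to an intended hour
#' that the generator verifies against the labeler itself (resampling a
#' bounded number of times on failure). Negative admissions keep systolic
#' pressure at or above 95 mmHg so they can transiently satisfy sepsis or
#' even severe-sepsis states but can never reach septic shock.
#'
#' @param n_admissions Number of admissions.
#' @param shock_fraction Fraction in `[0, 1]` of admissions that develop
#'   septic shock.
#' @param stay_length_range Min/max stay length in whole hours (min >= 8;
#'   labeling windows need history).
#' @param missingness_rate Per feature-hour probability in `[0, 1)` that a
#'   measurement is not recorded (missing completely at random). Vital
#'   signs critical to the engineered deterioration are always recorded
#'   from deterioration start in positive admissions, and urine output is
#'   charted hourly throughout (as in routine ICU care).
#' @param missingness_mode `"mcar"` (default) or `"block"`: in block mode
#'   laboratory features are only measured every `block_interval` hours
#'   (plus MCAR thinning), emulating scheduled lab draws; vitals stay MCAR.
#' @param block_interval Hours between lab draws in block mode.
#' @param deterioration_params List of drift/noise magnitudes (units of
#'   each feature): `ramp_range` (hours of pre-onset deterioration),
#'   `temp_peak` (degC), `hr_peak` (beats/min), `rr_peak` (breaths/min),
#'   `sbp_shock` (mmHg, post-onset systolic level), `lactate_peak`
#'   (mmol/L), `noise_scale` (multiplier on all measurement noise SDs).
#' @param infection_rate_negatives Fraction of negative admissions given an
#'   infection-suspicion interval (they may reach sepsis states).
#' @param max_retries Resampling attempts per admission before the
#'   generator gives up with a configuration error.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_admissions = 100, shock_fraction = 0.3,
                          stay_length_range = c(24, 96),
                          missingness_rate = 0.3,
                          missingness_mode = c("mcar", "block"),
                          block_interval = 4,
                          deterioration_params = list(),
                          infection_rate_negatives = 0.3,
                          max_retries = 20, seed = 1L) {
  missingness_mode <- match.arg(missingness_mode)
  stopifnot(n_admissions >= 1,
            shock_fraction >= 0, shock_fraction <= 1,
            length(stay_length_range) == 2,
            stay_length_range[1] >= 8,
            stay_length_range[1] <= stay_length_range[2],
            missingness_rate >= 0, missingness_rate < 1)
  det <- utils::modifyList(list(
    ramp_range = c(8, 16), temp_peak = 39.0, hr_peak = 115, rr_peak = 24,
    sbp_shock = 80, lactate_peak = 3.5, noise_scale = 1
  ), deterioration_params)
  structure(list(n_admissions = as.integer(n_admissions),
                 shock_fraction = shock_fraction,
                 stay_length_range = as.integer(stay_length_range),
                 missingness_rate = missingness_rate,
                 missingness_mode = missingness_mode,
                 block_interval = as.integer(block_interval),
                 deterioration_params = det,
                 infection_rate_negatives = infection_rate_negatives,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# baseline measurement noise SDs (feature units), before noise_scale
synthetic_noise_sd <- function() {
  c(heart_rate = 5, sbp = 5, dbp = 4, temperature = 0.22,
    respiratory_rate = 1.6, spo2 = 0.8, gcs = 0.3, wbc = 700, paco2 = 2.5,
    lactate = 0.12, creatinine = 0.07, bilirubin = 0.07, platelets = 16000,
    inr = 0.05, pao2_fio2 = 25, bun = 2.5, glucose = 14, sodium = 2.2,
    potassium = 0.22, hemoglobin = 0.6, bicarbonate = 1.1)
}

lab_features <- function() {
  c("wbc", "paco2", "lactate", "creatinine", "bilirubin", "platelets",
    "inr", "pao2_fio2", "bun", "glucose", "sodium", "potassium",
    "hemoglobin", "bicarbonate")
}

#' Generate a synthetic ICU cohort
#'
#' See [cohort_config()] for the generative model. Every admission's
#' intended outcome is verified by running the package's own hourly
#' labeler on the generated events; positives must yield septic shock at
#' exactly the engineered onset hour and negatives must never reach
#' septic shock, otherwise the admission is resampled (bounded retries).
#'
#' @param config A [cohort_config()].
#' @param ranges Feature table used for clamping values into clinical
#'   range and for the self-check labeling run.
#' @return A [sepsis_cohort()] whose `meta` carries `outcome_label` and
#'   `intended_onset_hour` (NA for negatives); the labeler reproduces both.
#' @export
generate_cohort <- function(config = cohort_config(),
                            ranges = default_feature_table()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_admissions
  n_pos <- round(config$shock_fraction * n)
  pos_idx <- if (n_pos > 0) sort(sample.int(n, n_pos)) else integer(0)

  ev_list <- vector("list", n)
  meta_list <- vector("list", n)
  inf_list <- vector("list", n)
  for (i in seq_len(n)) {
    positive <- i %in% pos_idx
    adm <- NULL
    for (try in seq_len(config$max_retries)) {
      cand <- simulate_admission(sprintf("adm%04d", i), positive, config, ranges)
      verdict <- check_admission(cand, ranges)
      ok <- if (positive) {
        isTRUE(verdict$shock) &&
          identical(verdict$onset_hour, cand$meta$intended_onset_hour)
      } else {
        !isTRUE(verdict$shock)
      }
      if (ok) {
        adm <- cand
        break
      }
    }
    if (is.null(adm)) {
      stop("could not generate a ", if (positive) "septic-shock" else "negative",
           " admission satisfying the labeling criteria after ",
           config$max_retries, " attempts; violated criterion: ",
           if (positive) "septic_shock onset at the engineered hour"
           else "absence of septic_shock")
    }
    ev_list[[i]] <- adm$events
    meta_list[[i]] <- adm$meta
    inf_list[[i]] <- adm$infections
  }
  events <- do.call(rbind, ev_list)
  events$event_id <- seq_len(nrow(events))
  events <- events[, c("event_id", "admission_id", "feature", "time_hours", "value")]
  rownames(events) <- NULL
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  infections <- do.call(rbind, inf_list)
  if (is.null(infections)) {
    infections <- data.frame(admission_id = character(), start_hour = numeric(),
                             end_hour = numeric())
  }
  rownames(infections) <- NULL
  sepsis_cohort(events, meta, infections)
}

# label one candidate admission with the package's own labeler
check_admission <- function(adm, ranges) {
  ev <- remove_outliers(adm$events, ranges)
  inf <- adm$infections
  if (is.null(inf)) {
    inf <- data.frame(admission_id = character(), start_hour = numeric(),
                      end_hour = numeric())
  }
  obs <- admission_observations(ev, adm$meta, inf, ranges)
  st <- label_admission(obs, adm$meta)
  list(shock = !is.na(st$onset_hour), onset_hour = st$onset_hour)
}

simulate_admission <- function(aid, positive, config, ranges) {
  det <- config$deterioration_params
  noise <- synthetic_noise_sd() * det$noise_scale
  stay <- sample(seq(config$stay_length_range[1], config$stay_length_range[2]), 1)
  hours <- seq_len(stay) - 1L
  age <- round(stats::runif(1, 18, 95))
  weight <- round(min(max(stats::rnorm(1, 80, 14), 45), 160), 1)
  meta <- data.frame(
    admission_id = aid, age = age, weight = weight, stay_hours = stay,
    flag_chronic_renal = stats::runif(1) < 0.08,
    flag_chronic_liver = stats::runif(1) < 0.06,
    flag_pneumonia = stats::runif(1) < 0.10,
    outcome_label = positive, intended_onset_hour = NA_integer_,
    stringsAsFactors = FALSE
  )

  feats <- names(noise)
  normals <- ranges$normal[match(feats, ranges$feature)]
  names(normals) <- feats
  # per-admission baseline offsets + hourly measurement noise
  base <- normals + stats::rnorm(length(feats), 0, noise / 2)
  vals <- matrix(rep(base, each = stay), nrow = stay,
                 dimnames = list(NULL, feats))
  vals <- vals + matrix(stats::rnorm(stay * length(feats), 0, rep(noise, each = stay)),
                        nrow = stay)

  infections <- NULL
  fluid_events <- NULL
  onset <- NA_integer_

  if (positive) {
    ramp <- sample(seq(det$ramp_range[1], det$ramp_range[2]), 1)
    onset <- sample(seq(max(12L, ramp + 4L), stay - 1L), 1)
    t_det <- onset - ramp
    frac <- pmax(0, pmin(1, (hours - t_det) / ramp))
    ramp_to <- function(x, peak) x + frac * (peak - x)
    vals[, "temperature"] <- ramp_to(vals[, "temperature"], det$temp_peak)
    vals[, "heart_rate"] <- ramp_to(vals[, "heart_rate"], det$hr_peak)
    vals[, "respiratory_rate"] <- ramp_to(vals[, "respiratory_rate"], det$rr_peak)
    vals[, "sbp"] <- ramp_to(vals[, "sbp"], 96)
    # organ dysfunction: lactate crosses 2.0 shortly before onset
    lf <- pmax(0, pmin(1, (hours - (onset - 4)) / 4))
    vals[, "lactate"] <- vals[, "lactate"] + lf * (det$lactate_peak - vals[, "lactate"])
    post <- hours >= onset
    # firm criteria at/after onset; no hypotension before it
    vals[!post, "sbp"] <- pmax(vals[!post, "sbp"], 92)
    vals[post, "sbp"] <- pmin(pmax(det$sbp_shock + stats::rnorm(sum(post), 0, 3), 45), 88)
    vals[post, "temperature"] <- pmax(vals[post, "temperature"], 38.3)
    vals[post, "heart_rate"] <- pmax(vals[post, "heart_rate"], 98)
    vals[post, "respiratory_rate"] <- pmax(vals[post, "respiratory_rate"], 22)
    vals[post, "lactate"] <- pmax(vals[post, "lactate"], 2.3)
    meta$intended_onset_hour <- as.integer(onset)
    infections <- data.frame(admission_id = aid,
                             start_hour = max(0, t_det - 2),
                             end_hour = stay, stringsAsFactors = FALSE)
    # resuscitation boluses make fluids adequate (>=1200 mL total) by onset
    fluid_events <- data.frame(
      time_hours = onset - c(3, 2, 1) + stats::runif(3, 0.05, 0.4),
      value = 500, stringsAsFactors = FALSE
    )
  } else {
    vals[, "sbp"] <- pmax(vals[, "sbp"], 95)
    if (stats::runif(1) < config$infection_rate_negatives && stay > 12) {
      a <- sample(seq(0, stay - 9), 1)
      infections <- data.frame(admission_id = aid, start_hour = a,
                               end_hour = min(stay, a + sample(8:24, 1)),
                               stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.3) {
      nb <- sample(1:3, 1)
      fluid_events <- data.frame(
        time_hours = sort(stats::runif(nb, 0, stay - 1)),
        value = round(stats::runif(nb, 100, 450)),
        stringsAsFactors = FALSE
      )
    }
  }

  # clamp into clinical range so only injected outliers fall outside
  lo <- ranges$lower[match(feats, ranges$feature)]
  hi <- ranges$upper[match(feats, ranges$feature)]
  for (j in seq_along(feats)) {
    vals[, j] <- pmin(pmax(vals[, j], lo[j]), hi[j])
  }

  keep <- matrix(stats::runif(stay * length(feats)) >= config$missingness_rate,
                 nrow = stay)
  if (config$missingness_mode == "block") {
    lab <- feats %in% lab_features()
    drawn <- hours %% config$block_interval == 0
    keep[, lab] <- keep[, lab] & drawn
  }
  # first hour fully observed (admission work-up); critical deterioration
  # vitals always charted once a positive admission starts deteriorating
  keep[1, ] <- TRUE
  if (positive) {
    crit <- c("temperature", "heart_rate", "respiratory_rate", "sbp", "lactate")
    keep[hours >= (onset - ramp), feats %in% crit] <- TRUE
  }

  idx <- which(keep, arr.ind = TRUE)
  events <- data.frame(
    admission_id = aid,
    feature = feats[idx[, 2]],
    time_hours = hours[idx[, 1]] + stats::runif(nrow(idx), -0.45, 0.45),
    value = round(vals[idx], 4),
    stringsAsFactors = FALSE
  )
  events$time_hours <- pmax(events$time_hours, 0)
  # hourly urine output (mL), always charted
  urine <- data.frame(
    admission_id = aid, feature = "urine_output",
    time_hours = hours + stats::runif(stay, -0.45, 0.45),
    value = round(pmax(stats::rnorm(stay, weight * 0.9, weight * 0.2), 5), 1),
    stringsAsFactors = FALSE
  )
  urine$time_hours <- pmax(urine$time_hours, 0)
  events <- rbind(events, urine)
  if (!is.null(fluid_events)) {
    events <- rbind(events, data.frame(
      admission_id = aid, feature = "fluid_bolus",
      time_hours = fluid_events$time_hours, value = fluid_events$value,
      stringsAsFactors = FALSE
    ))
  }
  events <- events[order(events$time_hours, events$feature), , drop = FALSE]
  events$event_id <- seq_len(nrow(events))  # provisional; reassigned cohort-wide
  list(events = events, meta = meta, infections = infections)
}

#' Inject out-of-range outlier values into an event table
#'
#' Corrupts a deterministic, seeded sample of events (exact count
#' `round(rate * n_events)`) by moving their values strictly outside the
#' clinical range of their feature (above or below, at random); all other
#' events are untouched. Used to exercise the outlier-removal step.
#'
#' @param events An events table.
#' @param rate Proportion of events to corrupt, in `[0, 1)`.
#' @param ranges Feature table supplying the ranges.
#' @param seed Integer seed.
#' @return The events table with corrupted values; attribute
#'   `outlier_ids` lists the affected `event_id`s.
#' @export
inject_outliers <- function(events, rate, ranges = default_feature_table(),
                            seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || !nrow(events)) {
    attr(events, "outlier_ids") <- integer(0)
    return(events)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n_out <- round(rate * nrow(events))
  pick <- sort(sample.int(nrow(events), n_out))
  idx <- match(events$feature[pick], ranges$feature)
  if (anyNA(idx)) stop("no clinical range for feature(s): ",
                       paste(unique(events$feature[pick][is.na(idx)]), collapse = ", "))
  lo <- ranges$lower[idx]
  hi <- ranges$upper[idx]
  span <- hi - lo
  above <- stats::runif(n_out) < 0.5
  new_val <- ifelse(above,
                    hi + span * stats::runif(n_out, 0.05, 0.5),
                    lo - span * stats::runif(n_out, 0.05, 0.5))
  # features with a hard physical floor at 0 can only be corrupted upward
  floor0 <- lo == 0
  new_val[floor0] <- hi[floor0] + span[floor0] * stats::runif(sum(floor0), 0.05, 0.5)
  events$value[pick] <- new_val
  attr(events, "outlier_ids") <- events$event_id[pick]
  events
}
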