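# Independent oracles and fixture builders shared across test files.

# Draw random hourly observations spanning both sides of every labeling
# threshold (uniformly over plausible + pathological ranges).
random_observations <- function(n) {
  data.frame(
    temperature = runif(n, 34, 40),
    heart_rate = runif(n, 60, 130),
    respiratory_rate = runif(n, 8, 30),
    paco2 = runif(n, 25, 45),
    wbc = runif(n, 2000, 16000),
    sbp = runif(n, 70, 130),
    lactate = runif(n, 0.5, 4),
    urine_output_2h_per_kg = runif(n, 0, 2),
    creatinine = runif(n, 0.5, 3.5),
    bilirubin = runif(n, 0.2, 3.5),
    platelets = runif(n, 5e4, 4e5),
    inr = runif(n, 0.8, 2.2),
    pao2_fio2 = runif(n, 150, 450),
    fluids_24h = runif(n, 0, 3000),
    fluids_total = runif(n, 0, 2500)
  )
}

random_meta <- function(n) {
  data.frame(
    admission_id = sprintf("r%03d", seq_len(n)),
    weight = runif(n, 50, 110),
    flag_chronic_renal = runif(n) < 0.3,
    flag_chronic_liver = runif(n) < 0.3,
    flag_pneumonia = runif(n) < 0.3
  )
}

# Flat, scalar restatement of the hourly criteria, written as one boolean
# expression per state, independent of the package's vectorized rule code.
oracle_label_hour <- function(o, m, infected) {
  sirs <- (o$temperature < 36 || o$temperature > 38) +
    (o$heart_rate > 90) +
    (o$respiratory_rate > 20 || o$paco2 < 32) +
    (o$wbc < 4000 || o$wbc > 12000)
  adequate <- (o$fluids_24h / m$weight >= 20) || (o$fluids_total >= 1200)
  septic <- sirs >= 2 && infected
  dysfunction <- o$sbp < 90 || o$lactate > 2.0 ||
    (o$urine_output_2h_per_kg < 0.5 && adequate) ||
    (o$creatinine > 2.0 && !m$flag_chronic_renal) ||
    (o$bilirubin > 2.0 && !m$flag_chronic_liver) ||
    o$platelets < 1e5 || o$inr > 1.5 ||
    (o$pao2_fio2 < 200 && m$flag_pneumonia) ||
    (o$pao2_fio2 < 250 && !m$flag_pneumonia)
  if (septic && dysfunction && o$sbp < 90 && adequate) {
    "septic_shock"
  } else if (septic && dysfunction) {
    "severe_sepsis"
  } else if (septic) {
    "sepsis"
  } else {
    "negative"
  }
}

# A fully-normal observation row (no criterion fires, fluids inadequate).
normal_obs <- function() {
  data.frame(
    temperature = 37, heart_rate = 80, respiratory_rate = 16, paco2 = 40,
    wbc = 8000, sbp = 115, lactate = 1.0, urine_output_2h_per_kg = 1.5,
    creatinine = 0.9, bilirubin = 0.7, platelets = 250000, inr = 1.0,
    pao2_fio2 = 400, fluids_24h = 0, fluids_total = 0
  )
}

plain_meta <- function(renal = FALSE, liver = FALSE, pneumonia = FALSE,
                       weight = 80) {
  data.frame(admission_id = "a1", age = 60, weight = weight, stay_hours = 24L,
             flag_chronic_renal = renal, flag_chronic_liver = liver,
             flag_pneumonia = pneumonia, outcome_label = FALSE)
}

# Minimal event-table builder
make_events <- function(feature, time_hours, value, admission_id = "a1") {
  n <- length(time_hours)
  data.frame(event_id = seq_len(n), admission_id = rep_len(admission_id, n),
             feature = rep_len(feature, n), time_hours = time_hours,
             value = rep_len(value, n), stringsAsFactors = FALSE)
}

# AUROC by exhaustive positive-negative pair counting (ties = 1/2)
auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Area under the empirical ROC curve by trapezoidal integration
auroc_trapezoid <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

# Brute-force HBO: scan the thresholded prediction series hour by hour
hbo_scan <- function(pred, onset, thr) {
  for (t in 0:onset) {
    if (t < length(pred) && pred[t + 1] >= thr) return(onset - t)
  }
  NA_real_
}

# Small cached synthetic cohort shared by expensive tests
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(n_admissions = 60,
                                              shock_fraction = 0.3,
                                              stay_length_range = c(24, 48),
                                              seed = 42))
    }
    cache
  }
})
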