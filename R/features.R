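#' Default clinical feature table
#'
#' The feature dictionary used throughout the pipeline: one row per model
#' feature with its unit, the normal clinical range used for outlier removal
#' (inclusive bounds), a reference "normal" value used as the labeling
#' fallback for features never observed during an admission, and flags for
#' binary features (passed through standardization unchanged) and event
#' features (features that occur in the raw long-format event stream, as
#' opposed to static demographics or trailing-window derivations).
#'
#' The set covers the vital signs and laboratory values named by the
#' SIRS/organ-dysfunction criteria plus routine ICU chemistry, demographics
#' and chronic-condition flags (roughly 30 inputs, mirroring TREWScore-style
#' feature sets). The range bounds are configuration, not ground truth:
#' users with site-specific conventions can supply an edited copy to any
#' function accepting a `ranges` argument.
#'
#' @return A data.frame with columns `feature`, `unit`, `lower`, `upper`,
#'   `normal`, `is_binary`, `is_event`.
#' @export
#' @examples
#' head(default_feature_table())
default_feature_table <- function() {
  tab <- rbind(
    # feature,            unit,        lower, upper,  normal, binary, event
    c("heart_rate",       "beats/min",  "20",  "250",  "78",   "0", "1"),
    c("sbp",              "mmHg",       "30",  "250",  "118",  "0", "1"),
    c("dbp",              "mmHg",       "15",  "150",  "70",   "0", "1"),
    c("temperature",      "degC",       "30",  "42.5", "36.8", "0", "1"),
    c("respiratory_rate", "breaths/min", "4",  "60",   "15",   "0", "1"),
    c("spo2",             "%",          "50",  "100",  "97",   "0", "1"),
    c("gcs",              "score",      "3",   "15",   "15",   "0", "1"),
    c("wbc",              "cells/uL",   "100", "200000", "8000", "0", "1"),
    c("paco2",            "mmHg",       "10",  "150",  "40",   "0", "1"),
    c("lactate",          "mmol/L",     "0.2", "30",   "1.0",  "0", "1"),
    c("creatinine",       "mg/dL",      "0.1", "30",   "0.9",  "0", "1"),
    c("bilirubin",        "mg/dL",      "0.05", "60",  "0.7",  "0", "1"),
    c("platelets",        "count/uL",   "1000", "2000000", "250000", "0", "1"),
    c("inr",              "ratio",      "0.4", "12",   "1.0",  "0", "1"),
    c("pao2_fio2",        "mmHg",       "30",  "650",  "430",  "0", "1"),
    c("bun",              "mg/dL",      "1",   "250",  "14",   "0", "1"),
    c("glucose",          "mg/dL",      "20",  "1200", "105",  "0", "1"),
    c("sodium",           "mEq/L",      "105", "180",  "140",  "0", "1"),
    c("potassium",        "mEq/L",      "1.5", "10",   "4.0",  "0", "1"),
    c("hemoglobin",       "g/dL",       "2",   "25",   "13.0", "0", "1"),
    c("bicarbonate",      "mEq/L",      "5",   "50",   "24",   "0", "1"),
    c("urine_output",     "mL",         "0",   "2000", "60",   "0", "1"),
    c("fluid_bolus",      "mL",         "0",   "5000", "0",    "0", "1"),
    # trailing-window derivations (computed from raw events, never imputed)
    c("urine_output_2h_per_kg", "mL/kg/2h", "0", "60", "1.5", "0", "0"),
    c("fluids_24h",       "mL",         "0",   "40000", "0",  "0", "0"),
    c("fluids_total",     "mL",         "0",   "200000", "0", "0", "0"),
    # static demographics / chronic-condition flags (broadcast per hour)
    c("age",              "years",      "0",   "120",  "60",   "0", "0"),
    c("weight",           "kg",         "20",  "300",  "80",   "0", "0"),
    c("flag_chronic_renal", "flag",     "0",   "1",    "0",    "1", "0"),
    c("flag_chronic_liver", "flag",     "0",   "1",    "0",    "1", "0"),
    c("flag_pneumonia",   "flag",       "0",   "1",    "0",    "1", "0")
  )
  out <- data.frame(
    feature = tab[, 1], unit = tab[, 2],
    lower = as.numeric(tab[, 3]), upper = as.numeric(tab[, 4]),
    normal = as.numeric(tab[, 5]),
    is_binary = tab[, 6] == "1", is_event = tab[, 7] == "1",
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$lower < out$upper | out$is_binary))
  out
}

#' Read or write a clinical feature table
#'
#' The on-disk schema is a plain CSV with the columns of
#' [default_feature_table()]. Validation is strict: all columns must be
#' present, features unique, and `lower < upper` for non-binary features.
#'
#' @param path CSV file path.
#' @param ranges A feature table (defaults to [default_feature_table()]).
#' @return `read_feature_table` returns the validated data.frame;
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_feature_table(tab)
  tab
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(ranges = default_feature_table(), path) {
  validate_feature_table(ranges)
  utils::write.csv(ranges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_feature_table <- function(tab) {
  need <- c("feature", "unit", "lower", "upper", "normal", "is_binary", "is_event")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$feature)) {
    stop("feature table has duplicated feature(s): ",
         paste(unique(tab$feature[duplicated(tab$feature)]), collapse = ", "))
  }
  bad <- !tab$is_binary & !(tab$lower < tab$upper)
  if (any(bad)) {
    stop("feature table has lower >= upper for: ",
         paste(tab$feature[bad], collapse = ", "))
  }
  invisible(tab)
}

# Features consumed by the hourly sepsis-state labeler.
criteria_features <- function() {
  c("temperature", "heart_rate", "respiratory_rate", "paco2", "wbc",
    "sbp", "lactate", "creatinine", "bilirubin", "platelets", "inr",
    "pao2_fio2")
}
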