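#' Remove events outside the normal clinical range
#'
#' Simple outlier rejection: an event is dropped when its value falls
#' strictly outside `[lower, upper]` for its feature (bounds inclusive, so
#' a value exactly at a bound is retained). Every event feature must have a
#' range entry.
#'
#' @param events An events table (see [sepsis_cohort()]).
#' @param ranges Feature table with `lower`/`upper` bounds.
#' @return The filtered events table, with attribute `removed_per_feature`
#'   (named integer vector of removal counts).
#' @export
remove_outliers <- function(events, ranges = default_feature_table()) {
  if (!nrow(events)) {
    out <- events
    attr(out, "removed_per_feature") <- integer(0)
    return(out)
  }
  idx <- match(events$feature, ranges$feature)
  if (anyNA(idx)) {
    stop("no clinical range entry for feature(s): ",
         paste(unique(events$feature[is.na(idx)]), collapse = ", "))
  }
  lo <- ranges$lower[idx]
  hi <- ranges$upper[idx]
  keep <- events$value >= lo & events$value <= hi
  removed <- table(factor(events$feature[!keep], levels = unique(events$feature)))
  out <- events[keep, , drop = FALSE]
  attr(out, "removed_per_feature") <- c(unclass(removed))
  out
}

#' Hourly grid container
#'
#' An `hourly_grid` holds one admission's hours-by-features numeric matrix
#' plus an observation mask. `mask[t, j]` is `TRUE` iff the value in that
#' cell came from at least one raw event binned to hour `t` (as opposed to
#' being imputed later). Hour 0 is the admission hour.
#'
#' @param admission_id Admission identifier.
#' @param values Numeric matrix, hours x features (NA = not yet imputed).
#' @param mask Logical matrix of the same shape.
#' @param features Character vector of feature (column) names.
#' @return An object of class `hourly_grid`.
#' @export
hourly_grid <- function(admission_id, values, mask, features) {
  stopifnot(is.matrix(values), is.matrix(mask),
            all(dim(values) == dim(mask)), ncol(values) == length(features))
  colnames(values) <- features
  colnames(mask) <- features
  structure(list(admission_id = admission_id, values = values, mask = mask,
                 features = features),
            class = "hourly_grid")
}

#' @export
print.hourly_grid <- function(x, ...) {
  cat(sprintf("<hourly_grid> %s: %d h x %d features, %.1f%% observed\n",
              x$admission_id, nrow(x$values), ncol(x$values),
              100 * mean(x$mask)))
  invisible(x)
}

#' Bin raw events to the nearest whole hour
#'
#' Each event is assigned to its closest whole hour after admission, ties
#' at .5 rounding half-up (so t = 2.5 h goes to hour 3). Multiple events of
#' one feature in the same bin are reduced to their arithmetic mean. Events
#' rounding to an hour at or beyond `stay_length` are ignored.
#'
#' @param events Events for one admission.
#' @param stay_length Stay length in whole hours; the grid has rows
#'   `0 .. stay_length - 1`.
#' @param features Feature (column) order; defaults to the sorted features
#'   present.
#' @param admission_id Identifier stored in the grid (defaults to the
#'   events' single admission id).
#' @return An [hourly_grid()] with `NA` in unobserved cells and a mask
#'   marking observed cells.
#' @export
bin_hourly <- function(events, stay_length, features = NULL, admission_id = NULL) {
  if (any(events$time_hours < 0)) stop("negative event times")
  if (is.null(features)) features <- sort(unique(events$feature))
  if (is.null(admission_id)) {
    admission_id <- if (nrow(events)) events$admission_id[1] else NA_character_
  }
  stay_length <- as.integer(stay_length)
  vals <- matrix(NA_real_, nrow = stay_length, ncol = length(features))
  mask <- matrix(FALSE, nrow = stay_length, ncol = length(features))
  ev <- events[events$feature %in% features, , drop = FALSE]
  if (nrow(ev)) {
    hr <- floor(ev$time_hours + 0.5)  # round half up
    ok <- hr < stay_length
    ev <- ev[ok, , drop = FALSE]
    hr <- hr[ok]
    if (nrow(ev)) {
      nf <- length(features)
      j <- match(ev$feature, features)
      cell <- hr * nf + j  # unique key: hr in 0..stay-1, j in 1..F
      means <- tapply(ev$value, cell, mean)
      key <- as.numeric(names(means))
      row <- (key - 1) %/% nf + 1L
      col <- key - (row - 1L) * nf
      idx <- cbind(row, col)
      vals[idx] <- as.numeric(means)
      mask[idx] <- TRUE
    }
  }
  hourly_grid(admission_id, vals, mask, features)
}

#' Zero-order-hold (forward-fill) imputation
#'
#' Fills each missing cell with the most recent observed value of the same
#' feature within the same admission. Cells with no prior observation are
#' left `NA` (they defer to the population-mean fallback). Never crosses
#' admission boundaries (grids are per-admission). Idempotent.
#'
#' @param grid An [hourly_grid()].
#' @return The grid with forward-filled values; the mask is unchanged (it
#'   keeps recording which cells were truly observed).
#' @export
impute_zoh <- function(grid) {
  vals <- grid$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    if (!anyNA(v)) next
    obs <- !is.na(v)
    if (!any(obs)) next
    idx <- cummax(ifelse(obs, seq_along(v), 0L))
    filled <- ifelse(idx > 0L, v[pmax(idx, 1L)], NA_real_)
    vals[, j] <- filled
  }
  grid$values <- vals
  grid
}

#' Population-mean fallback imputation
#'
#' Replaces values still missing after zero-order hold (features with no
#' previously recorded measurement in the admission) with the population
#' mean of the feature. After this step the grid is dense.
#'
#' @param grid An [hourly_grid()].
#' @param stats A `population_stats` object covering all grid features.
#' @return The dense grid.
#' @export
impute_population_mean <- function(grid, stats) {
  idx <- match(grid$features, stats$feature)
  if (anyNA(idx)) {
    stop("population stats missing for feature(s): ",
         paste(grid$features[is.na(idx)], collapse = ", "))
  }
  mu <- stats$mean[idx]
  for (j in seq_len(ncol(grid$values))) {
    miss <- is.na(grid$values[, j])
    if (any(miss)) grid$values[miss, j] <- mu[j]
  }
  grid
}

#' Per-feature population statistics
#'
#' Mean and standard deviation (sample SD, n-1 denominator) per feature,
#' computed over *observed* (mask-true) cells only, restricted to a stated
#' admission set. To avoid information leakage, cross-validation computes
#' these on training folds only and applies them to validation/test data.
#'
#' @param grids List of [hourly_grid()] objects.
#' @param ranges Feature table (identifies binary features, which need no
#'   positive SD).
#' @param scope Optional character vector of admission ids to restrict to;
#'   recorded in the result for provenance.
#' @return A data.frame of class `population_stats` with columns `feature`,
#'   `mean`, `sd`, `n_obs` and attribute `scope`.
#' @export
compute_population_stats <- function(grids, ranges = default_feature_table(),
                                     scope = NULL) {
  if (!is.null(scope)) {
    grids <- Filter(function(g) g$admission_id %in% scope, grids)
  }
  if (!length(grids)) stop("empty admission scope for population stats")
  features <- grids[[1]]$features
  mu <- sdv <- nobs <- numeric(length(features))
  for (j in seq_along(features)) {
    obs <- unlist(lapply(grids, function(g) g$values[g$mask[, j], j]),
                  use.names = FALSE)
    obs <- obs[!is.na(obs)]
    if (!length(obs)) stop("feature with zero observed values in scope: ",
                           features[j])
    mu[j] <- mean(obs)
    sdv[j] <- if (length(obs) > 1) stats::sd(obs) else 0
    nobs[j] <- length(obs)
  }
  is_bin <- ranges$is_binary[match(features, ranges$feature)]
  is_bin[is.na(is_bin)] <- FALSE
  degen <- !is_bin & sdv <= 0
  if (any(degen)) {
    stop("zero standard deviation for non-binary feature(s): ",
         paste(features[degen], collapse = ", "))
  }
  out <- data.frame(feature = features, mean = mu, sd = sdv, n_obs = nobs,
                    stringsAsFactors = FALSE)
  class(out) <- c("population_stats", "data.frame")
  attr(out, "scope") <- scope
  out
}

#' Standardize (or invert) an hourly grid
#'
#' Non-binary features are mapped to `(x - mean) / sd` with the population
#' statistics supplied (a standard-Gaussian rescaling); binary features
#' pass through unchanged. `unstandardize` inverts the map.
#'
#' @param grid A dense [hourly_grid()].
#' @param stats `population_stats` covering all features.
#' @param ranges Feature table (identifies binary features).
#' @return The transformed grid.
#' @export
standardize <- function(grid, stats, ranges = default_feature_table()) {
  scale_grid(grid, stats, ranges, invert = FALSE)
}

#' @rdname standardize
#' @export
unstandardize <- function(grid, stats, ranges = default_feature_table()) {
  scale_grid(grid, stats, ranges, invert = TRUE)
}

scale_grid <- function(grid, stats, ranges, invert) {
  idx <- match(grid$features, stats$feature)
  if (anyNA(idx)) {
    stop("population stats missing for feature(s): ",
         paste(grid$features[is.na(idx)], collapse = ", "))
  }
  is_bin <- ranges$is_binary[match(grid$features, ranges$feature)]
  is_bin[is.na(is_bin)] <- FALSE
  mu <- stats$mean[idx]
  sdv <- stats$sd[idx]
  if (any(!is_bin & sdv <= 0)) {
    stop("zero standard deviation for non-binary feature(s): ",
         paste(grid$features[!is_bin & sdv <= 0], collapse = ", "))
  }
  for (j in seq_len(ncol(grid$values))) {
    if (is_bin[j]) next
    grid$values[, j] <- if (invert) {
      grid$values[, j] * sdv[j] + mu[j]
    } else {
      (grid$values[, j] - mu[j]) / sdv[j]
    }
  }
  grid
}

#' Trailing-window fluid and urine quantities
#'
#' Computes, for each whole hour `h` of the stay, physically-windowed
#' summaries from raw (pre-binning) event times: total fluid bolus volume
#' over the trailing 24 h (`(h-24, h]`), cumulative fluid volume since
#' admission (`[0, h]`), and urine output over the trailing 2 h
#' (`(h-2, h]`) per kilogram body weight. These are derived before any
#' imputation because window semantics are physical, not grid artifacts;
#' hours with no urine events in the window count as 0 mL.
#'
#' @param events Raw events for one admission (features `fluid_bolus` and
#'   `urine_output` are used; others ignored).
#' @param hours Integer vector of hour indices (0-based).
#' @param weight Body weight in kg.
#' @return data.frame with columns `fluids_24h`, `fluids_total`,
#'   `urine_output_2h_per_kg`, one row per hour.
#' @export
trailing_windows <- function(events, hours, weight) {
  fl <- events[events$feature == "fluid_bolus", , drop = FALSE]
  ur <- events[events$feature == "urine_output", , drop = FALSE]
  win_sum <- function(ev, h, lo) {
    if (!nrow(ev)) return(0)
    sum(ev$value[ev$time_hours > lo & ev$time_hours <= h])
  }
  fluids_24h <- vapply(hours, function(h) win_sum(fl, h, h - 24), 0)
  fluids_total <- vapply(hours, function(h) {
    if (!nrow(fl)) 0 else sum(fl$value[fl$time_hours <= h])
  }, 0)
  urine_2h <- vapply(hours, function(h) win_sum(ur, h, h - 2), 0)
  data.frame(fluids_24h = fluids_24h, fluids_total = fluids_total,
             urine_output_2h_per_kg = urine_2h / weight)
}

#' Build model-input hourly grids for a cohort
#'
#' Assembles, per admission, the full model feature grid: event features
#' binned to the hour ([bin_hourly()]) and forward-filled
#' ([impute_zoh()]); trailing-window fluid/urine derivations
#' ([trailing_windows()]); and static demographics and chronic-condition
#' flags broadcast across hours. Derived and static columns are marked
#' observed in the mask. Population-mean imputation and standardization are
#' *not* applied here — they depend on fold-scoped statistics and are
#' applied by the caller (see [run_cross_validation()]).
#'
#' @param cohort A `sepsis_cohort`.
#' @param ranges Feature table; its rows define the model feature set and
#'   clinical ranges.
#' @return Named list (by admission id) of [hourly_grid()] objects.
#' @export
build_grids <- function(cohort, ranges = default_feature_table()) {
  validate_cohort(cohort)
  ev <- remove_outliers(cohort$events, ranges)
  # fluid boluses are episodic orders, not an hourly signal: they reach the
  # model through the trailing-window features, not as a grid column
  event_feats <- setdiff(ranges$feature[ranges$is_event], "fluid_bolus")
  static_feats <- c("age", "weight", "flag_chronic_renal",
                    "flag_chronic_liver", "flag_pneumonia")
  derived_feats <- c("urine_output_2h_per_kg", "fluids_24h", "fluids_total")
  all_feats <- setdiff(ranges$feature, "fluid_bolus")
  out <- vector("list", nrow(cohort$meta))
  names(out) <- cohort$meta$admission_id
  for (i in seq_len(nrow(cohort$meta))) {
    meta_i <- cohort$meta[i, , drop = FALSE]
    aid <- meta_i$admission_id
    stay <- meta_i$stay_hours
    hours <- seq_len(stay) - 1L
    ev_i <- ev[ev$admission_id == aid, , drop = FALSE]
    g <- bin_hourly(ev_i, stay_length = stay, features = event_feats,
                    admission_id = aid)
    g <- impute_zoh(g)
    tw <- trailing_windows(ev_i, hours, meta_i$weight)
    vals <- matrix(NA_real_, nrow = stay, ncol = length(all_feats))
    mask <- matrix(TRUE, nrow = stay, ncol = length(all_feats))
    colnames(vals) <- colnames(mask) <- all_feats
    vals[, event_feats] <- g$values
    mask[, event_feats] <- g$mask
    vals[, derived_feats] <- as.matrix(tw[, derived_feats])
    vals[, "age"] <- meta_i$age
    vals[, "weight"] <- meta_i$weight
    vals[, "flag_chronic_renal"] <- as.numeric(meta_i$flag_chronic_renal)
    vals[, "flag_chronic_liver"] <- as.numeric(meta_i$flag_chronic_liver)
    vals[, "flag_pneumonia"] <- as.numeric(meta_i$flag_pneumonia)
    out[[i]] <- hourly_grid(aid, vals, mask, all_feats)
  }
  out
}

#' Serialize an hourly grid to CSV
#'
#' Writes `<admission_id>.csv` (hour + one column per feature) and a
#' sidecar `<admission_id>_mask.csv` with the observation mask.
#'
#' @param grid An [hourly_grid()].
#' @param dir Output directory.
#' @return File path of the values CSV, invisibly.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(hour = seq_len(nrow(grid$values)) - 1L, grid$values,
                   check.names = FALSE)
  p <- file.path(dir, paste0(grid$admission_id, ".csv"))
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  mdf <- data.frame(hour = df$hour, grid$mask * 1L, check.names = FALSE)
  utils::write.csv(mdf, file.path(dir, paste0(grid$admission_id, "_mask.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(p)
}
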