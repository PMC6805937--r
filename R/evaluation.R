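#' AUROC by the rank (Wilcoxon) formulation
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half — identical to the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) true labels; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC needs both classes (got ", n_pos, " positives, ",
         n_neg, " negatives)")
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' One point per distinct score threshold (prediction positive when
#' `score >= threshold`), plus the (0,0) endpoint; the curve is monotone
#' non-decreasing from (0,0) to (1,1).
#'
#' @inheritParams auroc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each distinct score
  out <- data.frame(threshold = s[last], fpr = fp[last] / n_neg,
                    tpr = tp[last] / n_pos)
  rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), out)
}

#' Stratified cross-validation fold assignment
#'
#' Sets aside a validation holdout (default 5% of admissions) and splits
#' the remainder into `k` disjoint folds, stratified by outcome so the
#' positive proportion of every fold is close to the global proportion.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param ids Admission identifiers.
#' @param labels Logical outcome per admission.
#' @param k Number of folds (default 6).
#' @param val_frac Validation holdout fraction (default 0.05).
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `validation` (ids) and `folds`
#'   (list of `k` id vectors).
#' @export
make_folds <- function(ids, labels, k = 6, val_frac = 0.05, seed = 1L) {
  labels <- as.logical(labels)
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  pos <- sample(ids[labels])
  neg <- sample(ids[!labels])
  n_val_pos <- round(val_frac * length(pos))
  n_val_neg <- round(val_frac * length(neg))
  if (length(pos) - n_val_pos < k || length(neg) - n_val_neg < k) {
    stop("cohort too small for a stratified ", k, "-fold split: ",
         length(pos), " positives / ", length(neg), " negatives")
  }
  validation <- c(utils::head(pos, n_val_pos), utils::head(neg, n_val_neg))
  if (n_val_pos > 0) pos <- pos[-seq_len(n_val_pos)]
  if (n_val_neg > 0) neg <- neg[-seq_len(n_val_neg)]
  # one continuous round-robin deal (positives first, then negatives):
  # both classes and the total fold sizes come out as even as possible
  combined <- c(pos, neg)
  fold_idx <- (seq_along(combined) - 1) %% k + 1
  folds <- lapply(seq_len(k), function(i) combined[fold_idx == i])
  structure(list(validation = validation, folds = folds, k = k,
                 val_frac = val_frac, seed = seed),
            class = "fold_assignment")
}

#' Percentile bootstrap confidence interval over fold-level metrics
#'
#' Resamples the per-fold metric values with replacement `n_boot` times,
#' takes the mean of each resample, and returns the percentile interval.
#' Deterministic given `seed`.
#'
#' @param values Numeric metric values (one per trained model instance).
#' @param n_boot Bootstrap resamples (warning below 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, n_boot = 2000, level = 0.95, seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values to bootstrap")
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(values, length(values), replace = TRUE))
  }, 0)
  alpha <- (1 - level) / 2
  out <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  names(out) <- c("lower", "upper")
  out
}

#' Hours before onset (HBO) of the first positive prediction
#'
#' The lead time between the model's first alarm (first hour with
#' probability at or above the operating threshold, at or before onset)
#' and septic-shock onset. Admissions that are never alarmed at or before
#' onset are not correctly predicted and return `NA` (they are excluded
#' from HBO summaries).
#'
#' @param pred Per-hour probability vector (hour 0 first).
#' @param onset_hour 0-based onset hour.
#' @param threshold Operating threshold in `[0, 1]`.
#' @return Hours before onset (>= 0), or `NA` if no qualifying alarm.
#' @export
compute_hbo <- function(pred, onset_hour, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (is.na(onset_hour)) stop("onset_hour is required (positive admissions only)")
  hours <- seq_along(pred) - 1L
  alarm <- hours[pred >= threshold & hours <= onset_hour]
  if (!length(alarm)) return(NA_real_)
  onset_hour - alarm[1]
}

#' Operating threshold at a target sensitivity
#'
#' Chooses the largest threshold whose admission-level sensitivity on the
#' supplied (validation) scores reaches the target — the operating point
#' used for HBO lead-time statistics.
#'
#' @param scores Admission-level scores (max per-hour probability).
#' @param labels Logical outcomes.
#' @param target_sensitivity Required true-positive rate (default 0.85).
#' @return Threshold value.
#' @export
choose_threshold <- function(scores, labels, target_sensitivity = 0.85) {
  labels <- as.logical(labels)
  pos <- sort(scores[labels], decreasing = TRUE)
  if (!length(pos)) stop("no positive admissions to set a threshold on")
  need <- ceiling(target_sensitivity * length(pos))
  pos[max(need, 1L)]
}

#' AUROC as a function of hours before septic-shock onset
#'
#' For each offset `h = 1..window`, computes the AUROC of positive
#' admissions' scores taken `h` hours before their onset against negative
#' admissions' admission-level scores (max per-hour probability over the
#' stay). Positives whose pre-onset history is shorter than `h` are
#' skipped for that offset (and counted in `n_pos`). The default mode
#' scores a positive by its probability at exactly hour `onset - h`; mode
#' `"window_max"` instead uses the maximum probability over the `h` hours
#' preceding onset.
#'
#' @param preds Named list of per-hour probability vectors (positives
#'   truncated at onset).
#' @param onsets Named integer vector of onset hours (NA for negatives).
#' @param labels Named logical outcome vector.
#' @param window Largest offset (default 48 h).
#' @param mode `"at"` (default) or `"window_max"`.
#' @return data.frame with columns `h`, `auroc`, `n_pos`, `n_neg`
#'   (`auroc` is `NA` when fewer than 2 positives remain at that offset).
#' @export
preonset_auroc_curve <- function(preds, onsets, labels, window = 48,
                                 mode = c("at", "window_max")) {
  mode <- match.arg(mode)
  labels <- as.logical(labels)
  ids <- names(preds)
  stopifnot(!is.null(ids), length(onsets) == length(preds),
            length(labels) == length(preds))
  neg_scores <- vapply(preds[!labels], max, 0)
  pos_ids <- ids[labels]
  if (any(is.na(onsets[pos_ids]))) {
    stop("positive admissions must have onset hours")
  }
  rows <- lapply(seq_len(window), function(h) {
    sc <- numeric(0)
    for (id in pos_ids) {
      on_h <- onsets[[id]]
      if (on_h - h < 0) next  # insufficient pre-onset history at this offset
      p <- preds[[id]]
      sc <- c(sc, if (mode == "at") {
        p[on_h - h + 1L]
      } else {
        max(p[(on_h - h + 1L):on_h])
      })
    }
    a <- if (length(sc) >= 2 && length(neg_scores) >= 2) {
      auroc(c(sc, neg_scores), c(rep(TRUE, length(sc)),
                                 rep(FALSE, length(neg_scores))))
    } else NA_real_
    data.frame(h = h, auroc = a, n_pos = length(sc),
               n_neg = length(neg_scores))
  })
  do.call(rbind, rows)
}

#' Six-fold cross-validated evaluation of the pipeline
#'
#' The full evaluation protocol: label the cohort hourly, build feature
#' grids, set aside a stratified validation holdout and split the rest
#' into `k` stratified folds; then train one model instance per fold on
#' the union of the other folds (population statistics computed on that
#' training set only), score the held-out fold, and pool the `k`
#' prediction sets. Reported: pooled test ROC/AUROC with a bootstrap CI
#' over the fold-level AUROCs, HBO lead times at an operating threshold
#' chosen on the validation holdout at `target_sensitivity`, and the
#' pre-onset AUROC curve over `preonset_window` hours with per-offset
#' bootstrap CIs over fold-level curves.
#'
#' @param cohort A labeled-able `sepsis_cohort`.
#' @param config An [lstm_config()]; default [desk_scale_preset()].
#' @param ranges Feature table.
#' @param k Folds (default 6).
#' @param val_frac Validation holdout fraction (default 0.05).
#' @param n_boot Bootstrap resamples for CIs.
#' @param target_sensitivity Sensitivity target for the HBO threshold.
#' @param preonset_window Offsets for the pre-onset curve (default 48 h).
#' @param seed Master seed; folds, per-fold training and bootstrap draw
#'   from distinct derived substreams.
#' @param labels Optional precomputed [label_cohort()] result.
#' @return An `eval_report` (see Details) with elements `auroc`,
#'   `auroc_ci`, `fold_aurocs`, `roc`, `hbo` (`values`, `median`, `iqr`),
#'   `preonset` (per-offset AUROC with CIs), `thresholds`, `folds`,
#'   `predictions`, `scores`, `outcomes`, `fold_of`, `models`.
#' @export
run_cross_validation <- function(cohort, config = desk_scale_preset(),
                                 ranges = default_feature_table(), k = 6,
                                 val_frac = 0.05, n_boot = 1000,
                                 target_sensitivity = 0.85,
                                 preonset_window = 48, seed = 1L,
                                 labels = NULL) {
  validate_cohort(cohort)
  if (is.null(labels)) labels <- label_cohort(cohort, ranges)
  onsets <- labels$onsets
  grids <- build_grids(cohort, ranges)
  ids <- names(grids)
  y <- onsets$shock[match(ids, onsets$admission_id)]
  names(y) <- ids
  folds <- make_folds(ids, y, k = k, val_frac = val_frac, seed = seed)
  for (i in seq_len(k)) {
    fy <- y[folds$folds[[i]]]
    if (length(unique(fy)) < 2) {
      stop("fold ", i, " lacks one outcome class; enlarge the cohort")
    }
  }

  predictions <- list()
  fold_of <- integer(0)
  fold_aurocs <- numeric(k)
  thresholds <- numeric(k)
  hbo_values <- numeric(0)
  fold_curves <- vector("list", k)
  models <- vector("list", k)

  for (i in seq_len(k)) {
    test_ids <- folds$folds[[i]]
    train_ids <- unlist(folds$folds[-i], use.names = FALSE)
    stats_i <- compute_population_stats(grids[train_ids], ranges,
                                        scope = train_ids)
    prep_tr <- prepare_sequences(grids[train_ids], onsets, stats_i, ranges)
    prep_te <- prepare_sequences(grids[test_ids], onsets, stats_i, ranges)
    prep_va <- if (length(folds$validation)) {
      prepare_sequences(grids[folds$validation], onsets, stats_i, ranges)
    }
    cfg_i <- config
    cfg_i$seed <- config$seed + 97L * i  # per-fold training substream
    fit <- lstm_train(prep_tr$x, prep_tr$y,
                      val_x = prep_va$x, val_y = prep_va$y,
                      config = cfg_i, features = ranges$feature,
                      stats = stats_i)
    models[[i]] <- fit
    preds_i <- lstm_forward(fit, prep_te$x)
    names(preds_i) <- test_ids
    predictions <- c(predictions, preds_i)
    fold_of <- c(fold_of, stats::setNames(rep(i, length(test_ids)), test_ids))

    scores_te <- vapply(preds_i, max, 0)
    fold_aurocs[i] <- auroc(scores_te, y[test_ids])
    thresholds[i] <- if (!is.null(prep_va) && any(prep_va$y)) {
      va_scores <- vapply(lstm_forward(fit, prep_va$x), max, 0)
      choose_threshold(va_scores, prep_va$y, target_sensitivity)
    } else {
      choose_threshold(scores_te, y[test_ids], target_sensitivity)
    }
    for (id in test_ids[y[test_ids]]) {
      hbo <- compute_hbo(preds_i[[id]], prep_te$onset[[id]], thresholds[i])
      if (!is.na(hbo)) hbo_values <- c(hbo_values, hbo)
    }
    fold_curves[[i]] <- preonset_auroc_curve(
      preds_i, prep_te$onset, y[test_ids], window = preonset_window)
  }

  scores <- vapply(predictions, max, 0)
  outcomes <- y[names(scores)]
  pooled_auroc <- auroc(scores, outcomes)
  roc <- roc_curve(scores, outcomes)
  ci <- bootstrap_ci(fold_aurocs, n_boot = n_boot, seed = seed + 7919L)

  onset_vec <- stats::setNames(onsets$onset_hour, onsets$admission_id)
  pooled_curve <- preonset_auroc_curve(predictions,
                                       onset_vec[names(predictions)],
                                       outcomes, window = preonset_window)
  curve_ci <- t(vapply(seq_len(preonset_window), function(h) {
    vals <- vapply(fold_curves, function(fc) fc$auroc[fc$h == h], 0)
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 2) {
      bootstrap_ci(vals, n_boot = n_boot, seed = seed + 7919L + h)
    } else c(lower = NA_real_, upper = NA_real_)
  }, c(lower = 0, upper = 0)))
  pooled_curve$ci_lower <- curve_ci[, "lower"]
  pooled_curve$ci_upper <- curve_ci[, "upper"]

  structure(list(
    auroc = pooled_auroc,
    auroc_ci = ci,
    fold_aurocs = fold_aurocs,
    roc = roc,
    hbo = list(values = hbo_values,
               median = if (length(hbo_values)) stats::median(hbo_values) else NA_real_,
               iqr = if (length(hbo_values)) {
                 stats::quantile(hbo_values, c(0.25, 0.75), names = FALSE)
               } else c(NA_real_, NA_real_)),
    preonset = pooled_curve,
    thresholds = thresholds,
    target_sensitivity = target_sensitivity,
    folds = folds,
    predictions = predictions,
    scores = scores,
    outcomes = outcomes,
    fold_of = fold_of,
    models = models,
    seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> pooled test AUROC",
      sprintf("%.4f (95%% CI %.4f-%.4f over %d folds)\n", x$auroc,
              x$auroc_ci["lower"], x$auroc_ci["upper"],
              length(x$fold_aurocs)))
  if (length(x$hbo$values)) {
    cat(sprintf("  HBO: median %.1f h (IQR %.1f-%.1f) over %d correctly predicted positives\n",
                x$hbo$median, x$hbo$iqr[1], x$hbo$iqr[2], length(x$hbo$values)))
  } else {
    cat("  HBO: no correctly predicted positives at the operating threshold\n")
  }
  pc <- x$preonset[!is.na(x$preonset$auroc), ]
  if (nrow(pc)) {
    cat(sprintf("  pre-onset AUROC: %.3f at 1 h -> %.3f at %d h before onset\n",
                pc$auroc[1], pc$auroc[nrow(pc)], pc$h[nrow(pc)]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (summary metrics) plus `roc.csv`, `hbo.csv` and
#' `preonset_auroc.csv`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    auroc = report$auroc,
    auroc_ci = as.list(report$auroc_ci),
    fold_aurocs = report$fold_aurocs,
    hbo_median = report$hbo$median,
    hbo_iqr = report$hbo$iqr,
    n_hbo = length(report$hbo$values),
    thresholds = report$thresholds,
    target_sensitivity = report$target_sensitivity,
    seed = report$seed
  )
  writeLines(jsonlite::toJSON(summary, digits = NA, auto_unbox = TRUE),
             file.path(dir, "report.json"))
  utils::write.csv(report$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  utils::write.csv(data.frame(hbo_hours = report$hbo$values),
                   file.path(dir, "hbo.csv"), row.names = FALSE)
  utils::write.csv(report$preonset, file.path(dir, "preonset_auroc.csv"),
                   row.names = FALSE)
  invisible(dir)
}
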