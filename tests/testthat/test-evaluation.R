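test_that("AUROC matches hand-derived values and the tie convention", {
  expect_equal(auroc(c(1, 2, 3, 10, 20), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # 4 positive-negative pairs: 0.35 beats 0.1, loses to 0.4; 0.8 beats both
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUROC equals trapezoidal area and brute-force pair counts", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)  # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1))     # coarse grid forces ties
    a <- auroc(scores, labels)
    expect_equal(a, auroc_pairs(scores, labels), tolerance = 1e-12)
    expect_equal(a, auroc_trapezoid(scores, labels), tolerance = 1e-12)
  }
})

test_that("our AUROC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- runif(60)
  labels <- runif(60) < 0.45
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(23)
  rc <- roc_curve(runif(40), runif(40) < 0.5)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(unlist(rc[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(rc[nrow(rc), c("fpr", "tpr")], use.names = FALSE),
               c(1, 1))
})

test_that("fold assignment is stratified, exhaustive and deterministic", {
  ids <- sprintf("a%03d", 1:120)
  labels <- rep(c(TRUE, FALSE, FALSE, FALSE), 30)  # 25% positive
  fa <- make_folds(ids, labels, k = 6, val_frac = 0.05, seed = 3)
  expect_length(fa$validation, 6)
  expect_identical(lengths(fa$folds), rep(19L, 6))
  all_ids <- c(fa$validation, unlist(fa$folds))
  expect_setequal(all_ids, ids)
  expect_identical(anyDuplicated(all_ids), 0L)
  global <- mean(labels)
  for (f in fa$folds) {
    expect_lt(abs(mean(labels[match(f, ids)]) - global), 0.05)
  }
  fb <- make_folds(ids, labels, k = 6, val_frac = 0.05, seed = 3)
  expect_identical(fa, fb)
  expect_error(make_folds(ids[1:10], labels[1:10], k = 6), "too small")
})

test_that("bootstrap intervals collapse on constants, nest and contain", {
  expect_equal(unname(bootstrap_ci(rep(0.8, 6), seed = 1)), c(0.8, 0.8))
  vals <- c(0.7, 0.75, 0.8, 0.82, 0.85, 0.9)
  ci95 <- bootstrap_ci(vals, n_boot = 2000, level = 0.95, seed = 5)
  ci99 <- bootstrap_ci(vals, n_boot = 2000, level = 0.99, seed = 5)
  expect_lte(ci95["lower"], mean(vals))
  expect_gte(ci95["upper"], mean(vals))
  expect_lte(ci99["lower"], ci95["lower"])
  expect_gte(ci99["upper"], ci95["upper"])
  expect_warning(bootstrap_ci(vals, n_boot = 50, seed = 1), "unstable")
  expect_error(bootstrap_ci(0.5), "at least 2")
})

test_that("HBO equals the brute-force threshold scan", {
  pred <- rep(0.1, 60)
  pred[11] <- 0.9  # hour 10
  expect_equal(compute_hbo(pred, onset_hour = 50, threshold = 0.5), 40)
  pred2 <- rep(0.1, 60); pred2[51] <- 0.9
  expect_equal(compute_hbo(pred2, 50, 0.5), 0)
  expect_true(is.na(compute_hbo(rep(0.1, 60), 50, 0.5)))
  expect_error(compute_hbo(pred, 50, 1.5), "threshold")
  set.seed(29)
  for (i in 1:50) {
    p <- runif(sample(10:40, 1))
    onset <- sample(seq_along(p), 1) - 1
    thr <- runif(1)
    expect_identical(compute_hbo(p, onset, thr), hbo_scan(p, onset, thr))
  }
})

test_that("pre-onset AUROC handles constant and separable predictors", {
  preds <- list(p1 = rep(0.5, 30), p2 = rep(0.5, 25), n1 = rep(0.5, 40),
                n2 = rep(0.5, 20))
  onsets <- c(p1 = 25, p2 = 20, n1 = NA, n2 = NA)
  labels <- c(p1 = TRUE, p2 = TRUE, n1 = FALSE, n2 = FALSE)
  flat <- preonset_auroc_curve(preds, onsets, labels, window = 10)
  expect_equal(flat$auroc, rep(0.5, 10))

  sep <- preds
  sep$p1[25] <- 0.99; sep$p2[20] <- 0.99  # hour onset-1 stands out
  curve <- preonset_auroc_curve(sep, onsets, labels, window = 1)
  expect_equal(curve$auroc, 1.0)

  # offsets beyond a positive's history are skipped and counted
  short <- preonset_auroc_curve(preds, c(p1 = 5, p2 = 20, n1 = NA, n2 = NA),
                                labels, window = 10)
  expect_equal(short$n_pos, c(rep(2, 5), rep(1, 5)))
})

test_that("cross-validation bookkeeping and pooled metrics are consistent", {
  co <- shared_cohort()
  cvrep <- run_cross_validation(co, config = desk_scale_preset(seed = 2),
                              k = 3, n_boot = 200, preonset_window = 12,
                              seed = 2)
  ids <- co$meta$admission_id
  tested <- names(cvrep$fold_of)
  expect_setequal(c(tested, cvrep$folds$validation), ids)
  expect_identical(anyDuplicated(tested), 0L)
  # every admission is scored by the model that did not train on it
  for (i in seq_along(cvrep$folds$folds)) {
    expect_setequal(tested[cvrep$fold_of == i], cvrep$folds$folds[[i]])
  }
  # pooled AUROC is reproducible from the persisted per-admission scores
  expect_equal(cvrep$auroc, auroc(cvrep$scores, cvrep$outcomes))
  expect_equal(cvrep$scores,
               vapply(cvrep$predictions[names(cvrep$scores)], max, 0))
  expect_true(cvrep$auroc >= cvrep$auroc_ci["lower"] - 1e-9 ||
                cvrep$auroc <= cvrep$auroc_ci["upper"] + 1e-9)
  expect_true(all(cvrep$hbo$values >= 0))
  # report serialization round-trips through the documented files
  dir <- tempfile()
  write_report(cvrep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "report.json", "roc.csv", "hbo.csv", "preonset_auroc.csv")))))
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(js$auroc, cvrep$auroc)
})
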