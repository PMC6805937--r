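test_that("shock_fraction = 0 yields a cohort with no septic-shock hours", {
  co <- generate_cohort(cohort_config(n_admissions = 10, shock_fraction = 0,
                                      stay_length_range = c(24, 36), seed = 1))
  lab <- label_cohort(co)
  expect_identical(nrow(co$meta), 10L)
  expect_false(any(lab$states$state == "septic_shock"))
  expect_false(any(lab$onsets$shock))
})

test_that("positives are drawn by count and verified against the labeler", {
  co <- generate_cohort(cohort_config(n_admissions = 20, shock_fraction = 0.5,
                                      stay_length_range = c(24, 48), seed = 7))
  lab <- label_cohort(co)
  expect_identical(sum(lab$onsets$shock), 10L)
  m <- merge(co$meta, lab$onsets, by = "admission_id")
  expect_identical(m$outcome_label, m$shock)
  pos <- m[m$outcome_label, ]
  expect_identical(pos$onset_hour, pos$intended_onset_hour)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_admissions = 8, shock_fraction = 0.25,
                       stay_length_range = c(24, 30), seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$meta, b$meta)
  expect_identical(a$infections, b$infections)
})

test_that("generated events lie inside the clinical ranges", {
  co <- shared_cohort()
  ranges <- default_feature_table()
  idx <- match(co$events$feature, ranges$feature)
  expect_false(anyNA(idx))
  expect_true(all(co$events$value >= ranges$lower[idx]))
  expect_true(all(co$events$value <= ranges$upper[idx]))
})

test_that("block missingness restricts lab draws to the schedule", {
  co <- generate_cohort(cohort_config(n_admissions = 6, shock_fraction = 0,
                                      stay_length_range = c(24, 30),
                                      missingness_mode = "block",
                                      block_interval = 6, seed = 3))
  labs <- co$events[co$events$feature == "platelets", ]
  hrs <- floor(labs$time_hours + 0.5)
  expect_true(all(hrs %% 6 == 0))
})

test_that("inject_outliers corrupts exactly the requested fraction", {
  co <- shared_cohort()
  ev <- co$events[seq_len(1000), ]
  same <- inject_outliers(ev, 0, seed = 2)
  expect_identical(same$value, ev$value)
  expect_length(attr(same, "outlier_ids"), 0)

  out <- inject_outliers(ev, 0.05, seed = 2)
  ids <- attr(out, "outlier_ids")
  expect_length(ids, 50)
  ranges <- default_feature_table()
  hit <- out[out$event_id %in% ids, ]
  idx <- match(hit$feature, ranges$feature)
  expect_true(all(hit$value < ranges$lower[idx] | hit$value > ranges$upper[idx]))
  untouched <- out[!out$event_id %in% ids, ]
  expect_identical(untouched$value, ev$value[!ev$event_id %in% ids])

  # round trip: the outlier filter removes exactly the corrupted events
  kept <- remove_outliers(out, ranges)
  expect_identical(sort(setdiff(out$event_id, kept$event_id)), sort(ids))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(shock_fraction = 1.2))
  expect_error(cohort_config(stay_length_range = c(4, 30)))
  expect_error(cohort_config(missingness_rate = 1))
})
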