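test_that("count_sirs applies each threshold and counts criteria once", {
  obs <- data.frame(
    temperature = c(39, 37, 35, 36.5),
    heart_rate = c(95, 80, 91, 90),
    respiratory_rate = c(18, 16, 21, 20),
    paco2 = c(40, 40, 30, 32),
    wbc = c(8000, 9000, 3000, 4000)
  )
  # row 3: RR and PaCO2 both abnormal but the criterion counts once;
  # row 4: every value exactly at a strict threshold -> nothing fires
  expect_identical(count_sirs(obs), c(2L, 0L, 4L, 0L))
})

test_that("sepsis requires >=2 SIRS criteria and suspected infection", {
  two <- data.frame(temperature = 39, heart_rate = 95, respiratory_rate = 16,
                    paco2 = 40, wbc = 8000)
  four <- data.frame(temperature = 35, heart_rate = 91, respiratory_rate = 21,
                     paco2 = 30, wbc = 3000)
  one <- data.frame(temperature = 39, heart_rate = 80, respiratory_rate = 16,
                    paco2 = 40, wbc = 8000)
  expect_true(is_sepsis(two, TRUE))
  expect_false(is_sepsis(four, FALSE))
  expect_false(is_sepsis(one, TRUE))
})

test_that("fluid adequacy boundaries are inclusive on both branches", {
  expect_true(fluid_adequate(1600, 900, 80))    # exactly 20 mL/kg
  expect_true(fluid_adequate(500, 1200, 80))    # exactly 1200 mL total
  expect_false(fluid_adequate(500, 1199, 80))
  expect_false(fluid_adequate(1599, 0, 80))
  expect_error(fluid_adequate(500, 500, 0), "weight")
})

test_that("organ dysfunction honours exclusions and the pneumonia split", {
  base <- normal_obs()
  lact <- base; lact$lactate <- 2.5
  expect_true(organ_dysfunction(lact, plain_meta(), FALSE))
  creat <- base; creat$creatinine <- 2.5
  expect_false(organ_dysfunction(creat, plain_meta(renal = TRUE), FALSE))
  expect_true(organ_dysfunction(creat, plain_meta(), FALSE))
  lung <- base; lung$pao2_fio2 <- 230
  expect_true(organ_dysfunction(lung, plain_meta(pneumonia = FALSE), FALSE))
  expect_false(organ_dysfunction(lung, plain_meta(pneumonia = TRUE), FALSE))
  expect_false(organ_dysfunction(base, plain_meta(), FALSE))
})

test_that("label_hour gates septic shock on hypotension plus adequate fluids", {
  obs <- normal_obs()
  obs$temperature <- 39; obs$heart_rate <- 95        # SIRS = 2
  obs$lactate <- 2.5; obs$sbp <- 85                  # dysfunction + hypotension
  adequate <- obs; adequate$fluids_total <- 1500
  expect_equal(as.character(label_hour(adequate, plain_meta(), TRUE)),
               "septic_shock")
  expect_equal(as.character(label_hour(obs, plain_meta(), TRUE)),
               "severe_sepsis")
  expect_equal(as.character(label_hour(adequate, plain_meta(), FALSE)),
               "negative")
})

test_that("label_hour matches the flat-boolean oracle on random observations", {
  set.seed(101)
  obs <- random_observations(1000)
  meta <- random_meta(1000)
  infected <- runif(1000) < 0.5
  expected <- vapply(seq_len(1000), function(i) {
    oracle_label_hour(obs[i, ], meta[i, ], infected[i])
  }, "")
  got <- vapply(seq_len(1000), function(i) {
    as.character(label_hour(obs[i, ], meta[i, ], infected[i]))
  }, "")
  expect_identical(got, expected)
})

test_that("worsening any single criterion never lowers the state", {
  worsen <- list(
    function(o) { o$temperature <- 39.5; o },
    function(o) { o$temperature <- 35; o },
    function(o) { o$heart_rate <- 130; o },
    function(o) { o$respiratory_rate <- 30; o },
    function(o) { o$paco2 <- 25; o },
    function(o) { o$wbc <- 2000; o },
    function(o) { o$wbc <- 16000; o },
    function(o) { o$sbp <- 70; o },
    function(o) { o$lactate <- 5; o },
    function(o) { o$urine_output_2h_per_kg <- 0.1; o },
    function(o) { o$creatinine <- 4; o },
    function(o) { o$bilirubin <- 4; o },
    function(o) { o$platelets <- 4e4; o },
    function(o) { o$inr <- 3; o },
    function(o) { o$pao2_fio2 <- 150; o },
    function(o) { o$fluids_24h <- 4000; o },
    function(o) { o$fluids_total <- 3000; o }
  )
  set.seed(7)
  obs <- random_observations(60)
  meta <- random_meta(60)
  for (i in seq_len(60)) {
    before <- label_hour(obs[i, ], meta[i, ], TRUE)
    for (w in worsen) {
      after <- label_hour(w(obs[i, ]), meta[i, ], TRUE)
      expect_gte(as.integer(after), as.integer(before))
    }
  }
})

test_that("chronic-condition flags only suppress their own sub-criterion", {
  set.seed(13)
  obs <- random_observations(300)
  meta <- random_meta(300)
  for (i in seq_len(300)) {
    m2 <- meta[i, ]; m2$flag_chronic_liver <- !m2$flag_chronic_liver
    a <- label_hour(obs[i, ], meta[i, ], TRUE)
    b <- label_hour(obs[i, ], m2, TRUE)
    if (!identical(a, b)) {
      # flipping the liver flag may only matter when bilirubin > 2.0
      expect_gt(obs$bilirubin[i], 2.0)
    }
  }
})

test_that("label_admission finds the first septic-shock hour", {
  obs <- do.call(rbind, replicate(24, normal_obs(), simplify = FALSE))
  obs$infection_suspected <- FALSE
  res <- label_admission(obs, plain_meta())
  expect_length(res$states, 24)
  expect_true(all(res$states == "negative"))
  expect_true(is.na(res$onset_hour))

  shock_row <- normal_obs()
  shock_row$temperature <- 39; shock_row$heart_rate <- 100
  shock_row$lactate <- 3; shock_row$sbp <- 80; shock_row$fluids_total <- 1500
  obs2 <- do.call(rbind, replicate(45, normal_obs(), simplify = FALSE))
  obs2 <- rbind(obs2[1:30, ], shock_row, obs2[31:39, ], shock_row,
                obs2[40:43, ])
  obs2$infection_suspected <- TRUE
  res2 <- label_admission(obs2, plain_meta())
  expect_identical(res2$onset_hour, 30L)  # hours are 0-based
  expect_equal(which(res2$states == "septic_shock"), c(31, 41))

  expect_error(label_admission(obs2[0, ], plain_meta()), "empty")
})
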