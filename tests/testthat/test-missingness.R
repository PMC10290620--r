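test_that("dropout probability is the inverse-logit of the linear predictor", {
  expect_equal(dropout_probability(35, 1, 0.6, 800, 0, missing_spec()), 0.5)
  expect_equal(dropout_probability(0, 0, 0, 0, 0, missing_spec(beta0 = -2.2)),
               1 / (1 + exp(2.2)), tolerance = 1e-12)
  expect_equal(round(dropout_probability(0, 0, 0, 0, 0,
                                         missing_spec(beta0 = -2.2)), 4),
               0.0998)
  # arm coefficient log(4) multiplies the odds by exactly 4
  spec <- missing_spec(beta0 = -1.5, beta1 = 0.01, beta5 = log(4))
  p0 <- dropout_probability(40, 1, 0.5, 700, 0, spec)
  p1 <- dropout_probability(40, 1, 0.5, 700, 1, spec)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), 4, tolerance = 1e-12)
  expect_error(dropout_probability(Inf, 0, 0, 0, 0, missing_spec()), "finite")
})

test_that("imposed dropout is monotone with jointly missing cost and utility", {
  tr <- generate_complete_trial(gen_params(n_subjects = 400), 11)
  spec <- missing_spec(beta0 = -1.2, beta5 = log(2))
  inc <- impose_dropout(tr, spec, 21)
  ms <- missing_summary(inc)
  expect_true(ms$monotone)
  expect_gt(ms$overall, 0)
  # baseline untouched
  expect_identical(inc[c("id", "trt", "age", "gender", "cT0", "uT0")],
                   tr[c("id", "trt", "age", "gender", "cT0", "uT0")])
  # joint missingness per wave
  for (j in 1:4)
    expect_identical(is.na(inc[[paste0("cT", j)]]),
                     is.na(inc[[paste0("uT", j)]]))
  # determinism
  expect_identical(inc, impose_dropout(tr, spec, 21))
})

test_that("zero dropout probability returns the trial unchanged", {
  tr <- generate_complete_trial(gen_params(n_subjects = 100), 12)
  inc <- impose_dropout(tr, missing_spec(beta0 = -40), 5)
  expect_equal(as.data.frame(inc), as.data.frame(tr))
})

test_that("dropout draws depend only on baseline data (MAR by construction)", {
  tr <- generate_complete_trial(gen_params(n_subjects = 300), 13)
  spec <- missing_spec(beta0 = -1, beta3 = -1, beta4 = 0.001, beta5 = log(2))
  inc1 <- impose_dropout(tr, spec, 99)
  # permute every follow-up value; the missingness pattern must not move
  tr2 <- tr
  perm <- rev(seq_len(nrow(tr)))
  for (col in c(paste0("cT", 1:4), paste0("uT", 1:4)))
    tr2[[col]] <- tr[[col]][perm]
  inc2 <- impose_dropout(tr2, spec, 99)
  expect_identical(is.na(inc1), is.na(inc2))
})

test_that("covariate-free calibration matches the closed-form hazard", {
  p <- gen_params()
  spec <- calibrate_missingness(p, 0.10, arm_odds_multiplier = 1,
                                covariate_effect_scale = 0)
  h <- 1 - (1 - 0.10)^(1 / 4)
  expect_equal(spec$beta[["beta0"]], qlogis(h), tolerance = 1e-6)
  expect_equal(unname(spec$beta[2:6]), rep(0, 5))
  expect_equal(round(h, 4), 0.026)
})

test_that("arm odds multipliers map to the logit coefficient", {
  spec <- calibrate_missingness(gen_params(), 0.10, arm_odds_multiplier = 4)
  expect_equal(spec$beta[["beta5"]], log(4), tolerance = 1e-12)
  expect_equal(round(log(4), 3), 1.386)
})

test_that("calibrated dropout hits its target on independent data", {
  p <- gen_params()
  spec25 <- calibrate_missingness(p, 0.25, arm_odds_multiplier = 2)
  # 500-subject trials across 50 independent dropout draws
  p500 <- gen_params(n_subjects = 500)
  pilot <- generate_complete_trial(p500, 303)
  realized <- vapply(1:50, function(s)
    missing_summary(impose_dropout(pilot, spec25, s))$overall, numeric(1))
  expect_lt(abs(mean(realized) - 0.25), 0.03)

  # analytic expected proportion on a large independent pilot, +- 0.01
  spec50 <- calibrate_missingness(p, 0.50, arm_odds_multiplier = 1)
  big <- generate_complete_trial(gen_params(n_subjects = 50000), 404)
  pr <- dropout_probability(big$age, big$gender, big$uT0, big$cT0, big$trt,
                            spec50)
  expect_lt(abs(mean(1 - (1 - pr)^4) - 0.50), 0.01)

  # intervention arm drops out more under a >1 odds multiplier
  inc <- impose_dropout(big, spec25, 7)
  per_arm <- missing_summary(inc)$per_arm
  expect_gt(per_arm[["1"]], per_arm[["0"]])
})

test_that("calibration rejects unattainable or invalid targets", {
  expect_error(calibrate_missingness(gen_params(), 0), "target_proportion")
  expect_error(calibrate_missingness(gen_params(), 1), "target_proportion")
  expect_error(calibrate_missingness(gen_params(), 0.25, n_pilot = 100),
               "n_pilot")
})

test_that("missing_summary counts a hand-built fixture correctly", {
  fx <- data.frame(id = 1:4, trt = c(0, 1, 0, 1), age = 40, gender = 0,
                   cT0 = 100, uT0 = 0.5,
                   cT1 = 1, cT2 = 1, cT3 = c(1, 1, NA, 1), cT4 = c(1, 1, NA, 1),
                   uT1 = 1, uT2 = 1, uT3 = c(1, 1, NA, 1), uT4 = c(1, 1, NA, 1))
  ms <- missing_summary(fx)
  expect_equal(ms$overall, 0.25)
  expect_equal(unname(ms$per_wave), c(0, 0, 0.25, 0.25))
  expect_equal(ms$n_complete, 3)
  expect_true(ms$monotone)

  complete <- generate_complete_trial(gen_params(n_subjects = 20), 1)
  expect_equal(missing_summary(complete)$overall, 0)
  all_gone <- impose_dropout(complete, missing_spec(beta0 = 40), 1)
  expect_equal(unname(missing_summary(all_gone)$per_wave), rep(1, 4))
})
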