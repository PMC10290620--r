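test_that("wide/long reshaping is a lossless round trip", {
  tr <- generate_complete_trial(gen_params(n_subjects = 30), 51)
  long <- reshape_long(tr)
  expect_equal(nrow(long), 30 * 4)
  back <- reshape_wide(long)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  inc <- impose_dropout(tr, missing_spec(beta0 = -1), 52)
  long2 <- reshape_long(inc)
  expect_equal(nrow(long2), 30 * 4)  # missing rows retained
  expect_equal(sum(is.na(long2$cost)), sum(is.na(inc[paste0("cT", 1:4)])))
  expect_equal(as.data.frame(reshape_wide(long2)), as.data.frame(inc))
  expect_error(reshape_long(data.frame(id = 1)), "required columns")
})

test_that("mixed model recovers an exact arm shift", {
  n <- 60
  set.seed(53)
  base <- data.frame(id = 1:n, trt = rep_len(0:1, n), age = 40, gender = 0,
                     cT0 = runif(n, 90, 110), uT0 = 0.5)
  b <- 25
  for (j in 1:4) {
    base[[paste0("cT", j)]] <- 10 + b * base$trt + rnorm(n, sd = 1e-4)
    base[[paste0("uT", j)]] <- 0.5
  }
  f <- fit_llm_outcome(reshape_long(base), "cost")
  expect_equal(f$d, rep(b, 4), tolerance = 1e-3)
  expect_lt(f$sigma2_eps, 1e-6)
})

test_that("mixed-model contrasts match the brute-force ML oracle", {
  tr <- generate_complete_trial(gen_params(n_subjects = 40), 77)
  long <- reshape_long(tr)
  for (outc in c("cost", "utility")) {
    f <- fit_llm_outcome(long, outc)
    mm <- llm_model_matrix(long, outc)
    o <- oracle_llm_ml(mm$X, mm$y, mm$id)
    names(o$beta) <- colnames(mm$X)
    d_oracle <- unname(o$beta[paste0("wave", 1:4, ":trt")])
    expect_equal(f$d, d_oracle, tolerance = 1e-5)
    expect_equal(f$sigma2_omega, o$sigma2_omega, tolerance = 1e-3)
    expect_equal(f$sigma2_eps, o$sigma2_eps, tolerance = 1e-3)
  }
})

test_that("totals combine per-wave contrasts with the right weights", {
  fake <- function(d, v) structure(list(d = d, vcov_d = diag(v, length(d))),
                                   class = "llm_fit")
  tot <- llm_totals(fake(rep(62.5, 4), 1), fake(rep(0.04, 4), 1e-4))
  expect_equal(tot$dc, 250)
  expect_equal(tot$dq, 0.04)
  # independent contrasts with equal variance v: Var(sum) = 4v
  expect_equal(tot$var_dc, 4)
  expect_equal(tot$var_dq, 4 * 1e-4 * 0.25^2)
  # trapezoid option downweights the final wave
  tot2 <- llm_totals(fake(rep(62.5, 4), 1), fake(rep(0.04, 4), 1e-4),
                     auc = "trapezoid")
  expect_lt(tot2$dq, tot$dq)
  expect_error(llm_totals(structure(list(d = 1, vcov_d = NULL),
                                    class = "llm_fit"),
                          fake(0.04, 1)), "covariance")
})

test_that("per-subject totals sum costs and integrate utilities", {
  fx <- data.frame(id = 1:3, trt = c(0, 1, 0), age = 40, gender = 1,
                   cT0 = 50, uT0 = 0.6,
                   cT1 = 100, cT2 = 100, cT3 = 100, cT4 = 100,
                   uT1 = c(0.8, 1, 0.5), uT2 = c(0.8, 1, 0.5),
                   uT3 = c(0.8, 1, 0.5), uT4 = c(0.8, 1, 0.5))
  tot <- aggregate_totals(fx)
  expect_equal(tot$total_cost, rep(400, 3))
  expect_equal(tot$qaly, c(0.8, 1, 0.5))
  fx$cT3[2] <- NA
  expect_error(aggregate_totals(fx), "missing")
})

test_that("FGLS equals the explicit kronecker-product oracle", {
  tot <- aggregate_totals(generate_complete_trial(gen_params(n_subjects = 50), 5))
  f <- fit_sur(tot)
  o <- oracle_sur_kron(tot)
  expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-8)
  expect_equal(unname(f$vcov), unname(o$vcov), tolerance = 1e-8)
  expect_equal(f$cov_dcdq, o$vcov[2, 7], tolerance = 1e-10)
})

test_that("with identical regressors SUR reproduces per-equation OLS exactly", {
  tot <- aggregate_totals(generate_complete_trial(gen_params(n_subjects = 80), 6))
  tot$uT0 <- tot$cT0  # both equations now share the same design matrix
  f <- fit_sur(tot)
  ols_c <- coef(lm(total_cost ~ trt + cT0 + age + gender, tot))
  ols_q <- coef(lm(qaly ~ trt + uT0 + age + gender, tot))
  expect_equal(unname(f$coefficients[1:5]), unname(ols_c), tolerance = 1e-9)
  expect_equal(unname(f$coefficients[6:10]), unname(ols_q), tolerance = 1e-9)
})

test_that("residual covariance respects Cauchy-Schwarz", {
  tot <- aggregate_totals(generate_complete_trial(gen_params(n_subjects = 200), 9))
  f <- fit_sur(tot)
  expect_lte(abs(f$sigma[1, 2]), sqrt(f$sigma[1, 1] * f$sigma[2, 2]))
})

test_that("strategies coincide where they must on complete data", {
  tr <- generate_complete_trial(gen_params(n_subjects = 150), 61)
  cfg <- imputation_config(m = 3, seed = 62)
  llm <- run_strategy(tr, "LLM")
  mi_llm <- run_strategy(tr, "MI-LLM", cfg)
  expect_equal(mi_llm$dc, llm$dc, tolerance = 1e-8)
  expect_equal(mi_llm$dq, llm$dq, tolerance = 1e-8)

  sur <- run_strategy(tr, "SUR-CCA")
  msur <- run_strategy(tr, "M-SUR")
  misur <- run_strategy(tr, "MI-SUR", cfg)
  expect_equal(msur$dc, sur$dc, tolerance = 1e-10)
  expect_equal(misur$dc, sur$dc, tolerance = 1e-8)
  expect_equal(misur$dq, sur$dq, tolerance = 1e-8)
  expect_equal(misur$var_dc, sur$var_dc, tolerance = 1e-6)
  expect_error(run_strategy(tr, "nope"), "unknown strategy")
})

test_that("complete-case analysis uses exactly the complete subjects", {
  tr <- generate_complete_trial(gen_params(n_subjects = 500), 63)
  spec <- calibrate_missingness(gen_params(), 0.25, arm_odds_multiplier = 2)
  inc <- impose_dropout(tr, spec, 64)
  cca <- run_strategy(inc, "SUR-CCA")
  expect_lt(cca$n, 500)
  expect_equal(cca$n, missing_summary(inc)$n_complete)
})

test_that("all strategy confidence intervals are symmetric about the estimate", {
  tr <- generate_complete_trial(gen_params(n_subjects = 300), 65)
  inc <- impose_dropout(tr, missing_spec(beta0 = -1.5, beta5 = log(2)), 66)
  cfg <- imputation_config(m = 3, seed = 67)
  for (s in strategies()) {
    est <- run_strategy(inc, s, cfg)
    expect_equal(mean(est$ci_dc), est$dc, tolerance = 1e-8)
    expect_equal(mean(est$ci_dq), est$dq, tolerance = 1e-8)
    expect_gt(est$var_dc, 0)
    expect_gt(est$var_dq, 0)
  }
})
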