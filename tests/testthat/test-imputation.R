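mini_trial <- function(cT1, uT1 = rep(0.5, length(cT1))) {
  n <- length(cT1)
  data.frame(id = seq_len(n), trt = rep_len(c(0, 1), n), age = 40, gender = 0,
             cT0 = 100, uT0 = 0.5, cT1 = cT1,
             cT2 = 1, cT3 = 1, cT4 = 1,
             uT1 = uT1, uT2 = 0.5, uT3 = 0.5, uT4 = 0.5)
}

test_that("mean imputation fills available-case column means", {
  tr <- mini_trial(c(1, 3, NA))
  expect_equal(mean_impute(tr)$cT1, c(1, 3, 2))
  tr2 <- mini_trial(c(2, 4, 6, NA, NA))
  expect_equal(mean_impute(tr2)$cT1, c(2, 4, 6, 4, 4))
  # identity on complete data
  tr3 <- mini_trial(c(1, 2, 3))
  expect_identical(mean_impute(tr3), tr3)
  expect_error(mean_impute(mini_trial(c(NA, NA, NA))), "no observed")
})

test_that("mean imputation shrinks the column standard deviation", {
  tr <- generate_complete_trial(gen_params(n_subjects = 300), 8)
  inc <- impose_dropout(tr, missing_spec(beta0 = -1), 9)
  filled <- mean_impute(inc)
  for (col in c("cT2", "uT3")) {
    expect_lte(sd(filled[[col]]), sd(inc[[col]], na.rm = TRUE))
    # observed cells untouched
    obs <- !is.na(inc[[col]])
    expect_identical(filled[[col]][obs], inc[[col]][obs])
  }
})

test_that("the number of imputations follows the missingness proportion", {
  expect_equal(as.integer(choose_m(0.10)), 10L)
  expect_equal(as.integer(choose_m(0.25)), 10L)
  expect_equal(as.integer(choose_m(0.50)), 20L)
  expect_equal(as.integer(choose_m(0.0001)), 10L)
  expect_equal(attr(choose_m(0.50), "loss_of_efficiency"), 0.025)
  expect_lt(attr(choose_m(0.50), "loss_of_efficiency"), 0.05)
  expect_error(choose_m(0), "missing_proportion")
})

test_that("Rubin's rules pool point estimates and variances", {
  p <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$B, 2)
  expect_equal(p$T, 1 + 1.5 * 2)
  p2 <- rubin_pool(c(5, 5, 5), c(2, 2, 2))
  expect_equal(p2$estimate, 5)
  expect_equal(p2$B, 0)
  expect_equal(p2$T, 2)
  p3 <- rubin_pool(c(0, 0, 0), c(2, 2, 2))
  expect_equal(p3$estimate, 0)
  expect_equal(p3$T, 2)
  expect_error(rubin_pool(1, 1), "at least two")
  # T >= W always, CI symmetric around the estimate
  set.seed(4)
  for (i in 1:20) {
    est <- rnorm(10); w <- rexp(10)
    pp <- rubin_pool(est, w)
    expect_gte(pp$T, pp$W)
    expect_equal(mean(pp$ci), pp$estimate)
  }
})

test_that("Barnard-Rubin df never exceeds the complete-data df", {
  p <- rubin_pool(c(1, 2, 4), c(1, 1.2, 0.8), df_com = 30)
  expect_lte(p$df, 30)
  expect_gt(p$df, 0)
})

test_that("PMM imputation preserves observed cells and draws from donors", {
  tr <- generate_complete_trial(gen_params(n_subjects = 400), 31)
  spec <- missing_spec(beta0 = -1.3, beta5 = log(2))
  inc <- impose_dropout(tr, spec, 32)
  cfg <- imputation_config(m = 3, seed = 33)
  imp <- mice_pmm(inc, cfg)
  expect_length(imp, 3)
  for (k in 1:3) {
    expect_false(anyNA(imp[[k]]))
    for (col in c("cT1", "cT3", "uT2", "uT4")) {
      obs <- !is.na(inc[[col]])
      expect_identical(imp[[k]][[col]][obs], inc[[col]][obs])
      # donor property within the arm stratum implies range preservation
      for (a in 0:1) {
        sel <- inc$trt == a & !obs
        expect_true(all(imp[[k]][[col]][sel] %in%
                          inc[[col]][inc$trt == a & obs]))
      }
    }
    expect_true(all(imp[[k]]$uT3 >= 0 & imp[[k]]$uT3 <= 1))
    expect_true(all(imp[[k]]$cT4 >= 0))
  }
  # deterministic given the seed
  imp2 <- mice_pmm(inc, cfg)
  expect_identical(lapply(imp, as.data.frame), lapply(imp2, as.data.frame))
})

test_that("imputing a complete trial returns identical copies", {
  tr <- generate_complete_trial(gen_params(n_subjects = 60), 34)
  imp <- mice_pmm(tr, imputation_config(m = 3, seed = 35))
  expect_identical(as.data.frame(imp[[1]]), as.data.frame(tr))
  expect_identical(as.data.frame(imp[[2]]), as.data.frame(tr))
})

test_that("PMM recovers the masked mean under MCAR (chained, non-monotone)", {
  tr <- generate_complete_trial(gen_params(n_subjects = 2000), 36)
  set.seed(37)
  mask <- sample(nrow(tr), 600)  # 30% missing at wave 2 only
  inc <- tr
  inc$cT2[mask] <- NA
  inc$uT2[mask] <- NA
  expect_false(missing_summary(inc)$monotone)
  imp <- mice_pmm(inc, imputation_config(m = 10, n_chain_iterations = 5,
                                         seed = 38))
  truth <- mean(tr$cT2[mask])
  imputed_means <- vapply(imp, function(d) mean(d$cT2[mask]), numeric(1))
  se <- sd(tr$cT2[mask]) / sqrt(length(mask))
  expect_lt(abs(mean(imputed_means) - truth), 3 * se)
})

test_that("imputation fails informatively when donors are scarce", {
  tr <- mini_trial(c(1, 2, NA, NA, NA, NA, NA, NA))
  tr$uT1 <- c(0.4, 0.6, rep(NA, 6))
  expect_error(mice_pmm(tr, imputation_config(m = 2, knn = 5, seed = 1)),
               "donors")
})
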