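#' Monotone MAR dropout specification
#'
#' The per-wave dropout hazard of subject i follows a logistic model on
#' baseline covariates and arm:
#' \deqn{logit(\pi_i) = \beta_0 + \beta_1 age_i + \beta_2 gender_i +
#'   \beta_3 uT0_i + \beta_4 cT0_i + \beta_5 trt_i}
#' so that missingness depends only on fully observed baseline data and
#' treatment allocation (missing at random by construction). The arm odds
#' multiplier is \eqn{e^{\beta_5}}.
#'
#' @param beta0,beta1,beta2,beta3,beta4 logit-scale coefficients for the
#'   intercept, age, gender, baseline utility and baseline cost.
#' @param beta5 logit-scale arm coefficient; \code{exp(beta5)} is the odds
#'   multiplier for the intervention arm.
#' @param target_proportion the missingness proportion (share of subjects
#'   with at least one missing follow-up wave) this spec was calibrated for;
#'   informational.
#' @return object of class \code{missing_spec}.
#' @export
missing_spec <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                         beta4 = 0, beta5 = 0, target_proportion = NA_real_) {
  b <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         beta4 = beta4, beta5 = beta5)
  if (any(!is.finite(b))) stop("all coefficients must be finite", call. = FALSE)
  spec <- list(beta = b, target_proportion = target_proportion,
               arm_odds_multiplier = exp(beta5))
  class(spec) <- "missing_spec"
  spec
}

#' @export
print.missing_spec <- function(x, ...) {
  cat("Monotone MAR dropout spec\n")
  cat("  per-wave hazard logit coefficients:\n")
  print(round(x$beta, 5))
  cat(sprintf("  arm odds multiplier: %.3g", x$arm_odds_multiplier))
  if (!is.na(x$target_proportion))
    cat(sprintf("  (calibrated target: %.0f%% incomplete subjects)",
                100 * x$target_proportion))
  cat("\n")
  invisible(x)
}

#' Per-wave dropout probability
#'
#' Inverse-logit of the dropout linear predictor for given baseline
#' covariates and arm.
#'
#' @param age,gender,uT0,cT0,trt covariate values (vectorised).
#' @param spec a \code{\link{missing_spec}}.
#' @return probabilities in (0, 1).
#' @examples
#' dropout_probability(40, 1, 0.5, 700, 0, missing_spec(beta0 = -2.2))
#' @export
dropout_probability <- function(age, gender, uT0, cT0, trt, spec) {
  stopifnot(inherits(spec, "missing_spec"))
  vals <- cbind(age, gender, uT0, cT0, trt)
  if (any(!is.finite(vals))) stop("covariates must be finite", call. = FALSE)
  b <- spec$beta
  eta <- b[["beta0"]] + b[["beta1"]] * age + b[["beta2"]] * gender +
    b[["beta3"]] * uT0 + b[["beta4"]] * cT0 + b[["beta5"]] * trt
  stats::plogis(eta)
}

#' Impose monotone MAR dropout on a complete trial
#'
#' Sequentially, for each follow-up wave, every subject still in the study
#' drops out with the probability given by \code{\link{dropout_probability}};
#' from the dropout wave onward both the cost and the utility value are set
#' to missing. Baseline columns are never touched, so every missing pattern
#' is monotone and cost/utility are missing jointly per wave.
#'
#' @param trial a complete trial (\code{\link{generate_complete_trial}}).
#' @param spec a \code{\link{missing_spec}}.
#' @param seed integer seed; deterministic given \code{(trial, spec, seed)}.
#' @return the trial with missing follow-up values (class
#'   \code{trial_data}).
#' @export
impose_dropout <- function(trial, spec, seed) {
  stopifnot(inherits(spec, "missing_spec"))
  nw <- n_waves(trial)
  if (anyNA(trial)) stop("input trial must be complete", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  p <- dropout_probability(trial$age, trial$gender, trial$uT0, trial$cT0,
                           trial$trt, spec)
  n <- nrow(trial)
  in_study <- rep(TRUE, n)
  out <- trial
  for (j in seq_len(nw)) {
    # fixed-length draw per wave keeps the stream independent of earlier
    # dropout outcomes (MAR by construction: only baseline data enter p)
    u <- stats::runif(n)
    drop_now <- in_study & (u < p)
    in_study <- in_study & !drop_now
    if (any(!in_study)) {
      gone <- !in_study
      for (k in j:nw) {
        out[gone, paste0("cT", k)] <- NA_real_
        out[gone, paste0("uT", k)] <- NA_real_
      }
    }
  }
  out
}

n_waves <- function(trial) {
  sum(grepl("^cT[1-9][0-9]*$", names(trial)))
}

#' Calibrate a dropout specification to a target missingness proportion
#'
#' Fixes \code{beta5 = log(arm_odds_multiplier)}, sets the covariate
#' coefficients to a standardized log-odds of \code{0.2 *
#' covariate_effect_scale} per standard deviation of each baseline predictor
#' (positive for age, gender and baseline costs, negative for baseline
#' utility: sicker, costlier subjects drop out more), and root-finds the
#' intercept so that the expected proportion of subjects with at least one
#' missing follow-up wave equals \code{target_proportion}. The expectation
#' is computed analytically, \eqn{1 - (1-\pi_i)^{n_{waves}}} averaged over a
#' generated pilot population, so the calibration itself is noise-free.
#'
#' @param params \code{\link{gen_params}} describing the population.
#' @param target_proportion desired share of incomplete subjects, in (0, 1).
#' @param arm_odds_multiplier odds multiplier for the intervention arm
#'   (4, 2 and 1 for the 10/25/50 percent scenarios).
#' @param covariate_effect_scale multiplier on the default standardized
#'   covariate log-odds of 0.2 per SD; 0 gives covariate-free dropout.
#' @param n_pilot pilot population size used both to estimate covariate SDs
#'   and to average the analytic dropout probability.
#' @param seed seed for the pilot population.
#' @return a calibrated \code{\link{missing_spec}}.
#' @examples
#' \donttest{
#' spec <- calibrate_missingness(gen_params(), 0.25, arm_odds_multiplier = 2)
#' }
#' @export
calibrate_missingness <- function(params, target_proportion,
                                  arm_odds_multiplier = 1,
                                  covariate_effect_scale = 1,
                                  n_pilot = 50000L, seed = 2001L) {
  validate_gen_params(params)
  if (!is.finite(target_proportion) ||
      target_proportion <= 0 || target_proportion >= 1)
    stop("target_proportion must lie strictly in (0, 1)", call. = FALSE)
  if (arm_odds_multiplier <= 0)
    stop("arm_odds_multiplier must be positive", call. = FALSE)
  if (n_pilot < 10000L) stop("n_pilot must be at least 10000", call. = FALSE)

  pp <- params
  pp$n_subjects <- as.integer(n_pilot)
  pilot <- generate_complete_trial(pp, seed)
  base_lo <- 0.2 * covariate_effect_scale
  betas <- c(
    beta1 = base_lo / stats::sd(pilot$age),
    beta2 = base_lo / max(stats::sd(pilot$gender), 1e-12),
    beta3 = -base_lo / stats::sd(pilot$uT0),
    beta4 = base_lo / stats::sd(pilot$cT0)
  )
  beta5 <- log(arm_odds_multiplier)
  nw <- params$n_waves

  expected_prop <- function(beta0) {
    spec <- missing_spec(beta0, betas[["beta1"]], betas[["beta2"]],
                         betas[["beta3"]], betas[["beta4"]], beta5)
    p <- dropout_probability(pilot$age, pilot$gender, pilot$uT0, pilot$cT0,
                             pilot$trt, spec)
    mean(1 - (1 - p)^nw)
  }
  root <- tryCatch(
    stats::uniroot(function(b0) expected_prop(b0) - target_proportion,
                   interval = c(-30, 30), tol = 1e-10),
    error = function(e) stop("calibration failed for target ",
                             target_proportion, ": ", conditionMessage(e),
                             call. = FALSE))
  achieved <- expected_prop(root$root)
  if (abs(achieved - target_proportion) > 0.01)
    stop(sprintf("calibration did not converge: expected proportion %.4f vs target %.4f",
                 achieved, target_proportion), call. = FALSE)
  missing_spec(root$root, betas[["beta1"]], betas[["beta2"]],
               betas[["beta3"]], betas[["beta4"]], beta5,
               target_proportion = target_proportion)
}

#' Summarise missingness in a trial
#'
#' @param trial a (possibly incomplete) trial table.
#' @return list with per-wave missing proportions, per-arm and overall
#'   proportions of incomplete subjects, and a monotone-pattern flag.
#' @export
missing_summary <- function(trial) {
  nw <- n_waves(trial)
  cmat <- as.matrix(trial[paste0("cT", seq_len(nw))])
  umat <- as.matrix(trial[paste0("uT", seq_len(nw))])
  miss <- is.na(cmat)
  joint <- identical(unname(miss), unname(is.na(umat)))
  # monotone: once missing, missing at all later waves
  monotone <- all(apply(miss, 1L, function(m) !is.unsorted(m))) && joint
  any_missing <- apply(miss, 1L, any)
  per_arm <- tapply(any_missing, trial$trt, mean)
  list(
    per_wave = colMeans(miss),
    overall = mean(any_missing),
    per_arm = per_arm,
    n_complete = sum(!any_missing),
    monotone = monotone
  )
}
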