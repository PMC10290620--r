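#' Data-generating parameters for a simulated trial
#'
#' Constructs and validates the parameter set that defines one simulated
#' two-arm trial with baseline covariates and four follow-up waves of costs
#' and utilities. Defaults reproduce the study conditions: 600 subjects,
#' 52:48 intervention:control allocation, a slight baseline imbalance in age
#' (+5 years) and gender (+0.40 male probability, capped at 1) in the
#' intervention arm, gamma-distributed right-skewed costs and utilities with
#' age/gender-dependent means, a -0.5 baseline cost-utility (copula)
#' correlation, per-wave arm effects of 62.5 euros and 0.04 utility, and
#' compound-symmetric follow-up correlations of 0.7 (costs) and 0.9
#' (utilities).
#'
#' Cost and utility "dispersions" are gamma dispersions on the identity-link
#' scale: a variable with mean \eqn{\mu} and dispersion \eqn{\phi} has
#' variance \eqn{\phi \mu^2} (shape \eqn{1/\phi}). Follow-up wave variances
#' are likewise relative to the wave-1 value.
#'
#' @param n_subjects number of subjects per trial.
#' @param p_intervention probability of allocation to the intervention arm.
#' @param age_mean_control mean age (years) in the control arm.
#' @param age_arm_shift additive age difference (years) in the intervention arm.
#' @param age_variance variance of age (years^2) before truncation.
#' @param age_bounds length-2 numeric, ages clipped to this range.
#' @param p_male_control probability of male gender in the control arm.
#' @param male_arm_shift additive shift in male probability for the
#'   intervention arm; the resulting probability is capped into [0, 1].
#' @param baseline_cost_coefs named numeric (intercept, age, gender) for the
#'   baseline cost mean in euros.
#' @param baseline_cost_dispersion gamma dispersion of baseline costs.
#' @param baseline_utility_coefs named numeric (intercept, age, gender) for
#'   the baseline utility mean.
#' @param baseline_utility_dispersion gamma dispersion of baseline utilities.
#' @param baseline_cost_utility_corr Gaussian-copula correlation between
#'   baseline costs and utilities, conditional on age and gender.
#' @param cost_effect_per_wave true per-wave cost difference (euros) between
#'   arms; the true total cost difference is \code{n_waves} times this.
#' @param utility_effect_per_wave true per-wave utility difference.
#' @param wave1_cost_coefs named numeric (age, gender) entering the wave-1
#'   cost mean in addition to the baseline cost and the arm effect.
#' @param wave1_utility_coefs named numeric (age, gender) for wave-1 utility.
#' @param followup_corr_costs compound-symmetry correlation of the wave-2..4
#'   cost perturbations.
#' @param followup_corr_utilities same for utilities.
#' @param followup_cost_variance relative variance (dispersion) of the
#'   wave-2..4 cost perturbations around the wave-1 value.
#' @param followup_utility_variance same for utilities.
#' @param n_waves number of follow-up waves.
#'
#' @return an object of class \code{gen_params} (a validated list).
#' @examples
#' p <- gen_params()
#' true_effects(p)
#' @export
gen_params <- function(n_subjects = 600,
                       p_intervention = 0.52,
                       age_mean_control = 40,
                       age_arm_shift = 5,
                       age_variance = 140,
                       age_bounds = c(18, 99),
                       p_male_control = 0.52,
                       male_arm_shift = 0.40,
                       baseline_cost_coefs = c(intercept = 50, age = 15, gender = 100),
                       baseline_cost_dispersion = 0.15,
                       baseline_utility_coefs = c(intercept = 0.2, age = 0.0045, gender = 0.025),
                       baseline_utility_dispersion = 0.002,
                       baseline_cost_utility_corr = -0.5,
                       cost_effect_per_wave = 62.5,
                       utility_effect_per_wave = 0.04,
                       wave1_cost_coefs = c(age = 1, gender = 10),
                       wave1_utility_coefs = c(age = 0.002, gender = 0.01),
                       followup_corr_costs = 0.7,
                       followup_corr_utilities = 0.9,
                       followup_cost_variance = 0.1,
                       followup_utility_variance = 0.005,
                       n_waves = 4L) {
  p <- list(
    n_subjects = as.integer(n_subjects),
    p_intervention = p_intervention,
    age_mean_control = age_mean_control,
    age_arm_shift = age_arm_shift,
    age_variance = age_variance,
    age_bounds = age_bounds,
    p_male_control = p_male_control,
    male_arm_shift = male_arm_shift,
    baseline_cost_coefs = baseline_cost_coefs,
    baseline_cost_dispersion = baseline_cost_dispersion,
    baseline_utility_coefs = baseline_utility_coefs,
    baseline_utility_dispersion = baseline_utility_dispersion,
    baseline_cost_utility_corr = baseline_cost_utility_corr,
    cost_effect_per_wave = cost_effect_per_wave,
    utility_effect_per_wave = utility_effect_per_wave,
    wave1_cost_coefs = wave1_cost_coefs,
    wave1_utility_coefs = wave1_utility_coefs,
    followup_corr_costs = followup_corr_costs,
    followup_corr_utilities = followup_corr_utilities,
    followup_cost_variance = followup_cost_variance,
    followup_utility_variance = followup_utility_variance,
    n_waves = as.integer(n_waves)
  )
  class(p) <- "gen_params"
  validate_gen_params(p)
  p
}

validate_gen_params <- function(p) {
  stopifnot(inherits(p, "gen_params"))
  probs <- c(p$p_intervention, p$p_male_control)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  corrs <- c(p$baseline_cost_utility_corr, p$followup_corr_costs,
             p$followup_corr_utilities)
  if (any(abs(corrs) >= 1))
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  disps <- c(p$baseline_cost_dispersion, p$baseline_utility_dispersion,
             p$followup_cost_variance, p$followup_utility_variance)
  if (any(disps <= 0))
    stop("dispersions must be positive", call. = FALSE)
  if (p$n_subjects < 1L || p$n_waves < 1L)
    stop("n_subjects and n_waves must be positive", call. = FALSE)
  if (length(p$age_bounds) != 2L || diff(p$age_bounds) <= 0)
    stop("age_bounds must be an increasing pair", call. = FALSE)
  invisible(p)
}

#' True estimands implied by a parameter set
#'
#' @param params a \code{\link{gen_params}} object.
#' @return list with \code{theta_cost} (total cost difference, euros) and
#'   \code{theta_qaly} (QALY difference under rectangle area-under-curve
#'   weights).
#' @export
true_effects <- function(params) {
  validate_gen_params(params)
  list(theta_cost = params$n_waves * params$cost_effect_per_wave,
       theta_qaly = params$utility_effect_per_wave)
}

# gamma draw with mean mu and dispersion phi (Var = phi * mu^2), from
# uniforms so a Gaussian copula can drive the dependence
qgamma_mean_disp <- function(u, mu, phi) {
  shape <- 1 / phi
  stats::qgamma(u, shape = shape, rate = shape / mu)
}

#' Generate one complete trial
#'
#' Simulates a complete (no missing values) two-arm trial: arm allocation,
#' age, gender, baseline costs/utilities from gamma margins linked by a
#' Gaussian copula, then four follow-up waves. Wave 1 is gamma-distributed
#' around a mean that adds the arm effect and age/gender terms to the
#' baseline value; waves 2-4 are the wave-1 value plus compound-symmetric
#' normal perturbations whose standard deviation scales with the wave-1
#' value. Utilities are truncated into [0, 1] and costs floored at 0.
#'
#' @param params a \code{\link{gen_params}} object.
#' @param seed integer seed; the output is a deterministic function of
#'   \code{(params, seed)} and the caller's RNG state is left untouched.
#' @return a \code{data.frame} of class \code{trial_data} with columns
#'   \code{id, trt, age, gender, cT0..cT4, uT0..uT4}.
#' @examples
#' tr <- generate_complete_trial(gen_params(n_subjects = 50), seed = 1)
#' range(tr$uT1)
#' @export
generate_complete_trial <- function(params, seed) {
  validate_gen_params(params)
  n <- params$n_subjects
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  trt <- stats::rbinom(n, 1L, params$p_intervention)
  if (min(sum(trt), n - sum(trt)) < 2L && n >= 4L)
    stop("degenerate allocation: fewer than 2 subjects in one arm", call. = FALSE)

  age <- stats::rnorm(n, params$age_mean_control + params$age_arm_shift * trt,
                      sqrt(params$age_variance))
  age <- pmin(pmax(age, params$age_bounds[1]), params$age_bounds[2])
  p_male <- pmin(pmax(params$p_male_control + params$male_arm_shift * trt, 0), 1)
  gender <- stats::rbinom(n, 1L, p_male)

  # baseline: gamma margins, Gaussian copula at the stated correlation
  rho <- params$baseline_cost_utility_corr
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  bc <- params$baseline_cost_coefs
  bu <- params$baseline_utility_coefs
  mu_c0 <- bc[["intercept"]] + bc[["age"]] * age + bc[["gender"]] * gender
  mu_u0 <- bu[["intercept"]] + bu[["age"]] * age + bu[["gender"]] * gender
  cT0 <- qgamma_mean_disp(stats::pnorm(z1), mu_c0, params$baseline_cost_dispersion)
  uT0 <- qgamma_mean_disp(stats::pnorm(z2), mu_u0, params$baseline_utility_dispersion)
  uT0 <- pmin(uT0, 1)

  wc <- params$wave1_cost_coefs
  wu <- params$wave1_utility_coefs
  mu_c1 <- cT0 + params$cost_effect_per_wave * trt +
    wc[["age"]] * age + wc[["gender"]] * gender
  mu_u1 <- uT0 + params$utility_effect_per_wave * trt +
    wu[["age"]] * age + wu[["gender"]] * gender
  cT1 <- qgamma_mean_disp(stats::runif(n), mu_c1, params$baseline_cost_dispersion)
  uT1 <- pmin(qgamma_mean_disp(stats::runif(n), mu_u1,
                               params$baseline_utility_dispersion), 1)

  nw <- params$n_waves
  cost <- matrix(NA_real_, n, nw)
  util <- matrix(NA_real_, n, nw)
  cost[, 1] <- cT1
  util[, 1] <- uT1
  if (nw > 1L) {
    k <- nw - 1L
    eps_c <- cs_normal(n, k, params$followup_corr_costs)
    eps_u <- cs_normal(n, k, params$followup_corr_utilities)
    sd_c <- sqrt(params$followup_cost_variance) * cT1
    sd_u <- sqrt(params$followup_utility_variance) * uT1
    cost[, -1] <- pmax(cT1 + eps_c * sd_c, 0)
    util[, -1] <- pmin(pmax(uT1 + eps_u * sd_u, 0), 1)
  }

  out <- data.frame(id = seq_len(n), trt = trt, age = age, gender = gender,
                    cT0 = cT0, uT0 = uT0)
  for (j in seq_len(nw)) out[[paste0("cT", j)]] <- cost[, j]
  for (j in seq_len(nw)) out[[paste0("uT", j)]] <- util[, j]
  out <- out[c("id", "trt", "age", "gender",
               paste0("cT", 0:nw), paste0("uT", 0:nw))]
  class(out) <- c("trial_data", "data.frame")
  out
}

# n x k standard-normal matrix with compound-symmetry correlation rho
cs_normal <- function(n, k, rho) {
  if (k == 1L) return(matrix(stats::rnorm(n), n, 1L))
  if (rho >= 0) {
    common <- stats::rnorm(n)
    idio <- matrix(stats::rnorm(n * k), n, k)
    sqrt(rho) * common + sqrt(1 - rho) * idio
  } else {
    # negative CS correlations (PSD only for rho >= -1/(k-1)): factor directly
    sigma <- matrix(rho, k, k)
    diag(sigma) <- 1
    matrix(stats::rnorm(n * k), n, k) %*% chol(sigma)
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Check that the generator hits its true effects
#'
#' Generates one large complete trial and fits the covariate-adjusted
#' two-equation model (\code{\link{fit_sur}}) on per-subject totals. At large
#' n the arm coefficients estimate the true total cost and QALY differences;
#' this is the generator's own calibration check.
#'
#' @param params a \code{\link{gen_params}} object (its \code{n_subjects} is
#'   ignored in favour of \code{n_large}).
#' @param n_large number of subjects, at least 1e5 for a tight check.
#' @param seed integer seed.
#' @return list with \code{theta_cost}, \code{se_cost}, \code{theta_qaly},
#'   \code{se_qaly} and the implied true values.
#' @export
check_calibration <- function(params, n_large = 200000L, seed = 1L) {
  validate_gen_params(params)
  params$n_subjects <- as.integer(n_large)
  trial <- generate_complete_trial(params, seed)
  totals <- aggregate_totals(trial)
  fit <- fit_sur(totals)
  tr <- true_effects(params)
  list(theta_cost = fit$dc, se_cost = sqrt(fit$var_dc),
       theta_qaly = fit$dq, se_qaly = sqrt(fit$var_dq),
       true_cost = tr$theta_cost, true_qaly = tr$theta_qaly)
}

#' @export
print.gen_params <- function(x, ...) {
  tr <- true_effects(x)
  cat("Trial data-generating parameters\n")
  cat(sprintf("  subjects: %d, waves: %d, P(intervention) = %.2f\n",
              x$n_subjects, x$n_waves, x$p_intervention))
  cat(sprintf("  per-wave effects: %.1f EUR, %.3f utility (totals: %.0f EUR, %.3f QALY)\n",
              x$cost_effect_per_wave, x$utility_effect_per_wave,
              tr$theta_cost, tr$theta_qaly))
  cat(sprintf("  follow-up correlations: %.2f costs, %.2f utilities\n",
              x$followup_corr_costs, x$followup_corr_utilities))
  invisible(x)
}
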