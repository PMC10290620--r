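#' Unconditional mean imputation
#'
#' Replaces every missing follow-up value by the mean of the available cases
#' of its column. The default pools both arms ("unconditional"); set
#' \code{by_arm = TRUE} for an arm-stratified variant.
#'
#' @param trial a trial table with missing follow-up values.
#' @param by_arm impute within arm strata instead of pooling.
#' @return the completed trial.
#' @examples
#' tr <- generate_complete_trial(gen_params(n_subjects = 30), seed = 1)
#' tr$cT2[1:3] <- NA; tr$uT2[1:3] <- NA
#' filled <- mean_impute(tr)
#' anyNA(filled)
#' @export
mean_impute <- function(trial, by_arm = FALSE) {
  out <- trial
  cols <- followup_columns(trial)
  for (col in cols) {
    x <- out[[col]]
    if (all(is.na(x)))
      stop("column ", col, " has no observed values to average", call. = FALSE)
    if (!anyNA(x)) next
    if (by_arm) {
      for (a in unique(out$trt)) {
        sel <- out$trt == a
        x[sel & is.na(x)] <- mean(x[sel], na.rm = TRUE)
      }
    } else {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    }
    out[[col]] <- x
  }
  out
}

followup_columns <- function(trial) {
  nw <- n_waves(trial)
  as.vector(rbind(paste0("cT", seq_len(nw)), paste0("uT", seq_len(nw))))
}

#' Configuration for multiple imputation
#'
#' @param m number of imputed datasets (at least 2).
#' @param knn donor-pool size for predictive mean matching.
#' @param stratify_by_arm impute separately within each treatment arm
#'   (the arm indicator is then not a predictor).
#' @param n_chain_iterations chained-equation sweeps for non-monotone
#'   patterns; a monotone pattern is completed in a single ordered sweep.
#' @param seed integer seed.
#' @return object of class \code{imputation_config}.
#' @export
imputation_config <- function(m = 10L, knn = 5L, stratify_by_arm = TRUE,
                              n_chain_iterations = 10L, seed = 1L) {
  if (m < 2L) stop("m must be at least 2", call. = FALSE)
  if (knn < 1L) stop("knn must be at least 1", call. = FALSE)
  cfg <- list(m = as.integer(m), knn = as.integer(knn),
              stratify_by_arm = isTRUE(stratify_by_arm),
              n_chain_iterations = as.integer(n_chain_iterations),
              seed = as.integer(seed))
  class(cfg) <- "imputation_config"
  cfg
}

#' Number of imputations by missingness proportion
#'
#' Returns 10 imputed datasets for up to 25 percent missing data and 20
#' above, keeping the loss of efficiency (approximated by
#' proportion missing / m) below \code{loe_max}.
#'
#' @param missing_proportion proportion of incomplete subjects, in (0, 1).
#' @param loe_max maximal acceptable loss of efficiency.
#' @return integer m, with attribute \code{loss_of_efficiency}.
#' @examples
#' choose_m(0.50)
#' @export
choose_m <- function(missing_proportion, loe_max = 0.05) {
  if (missing_proportion <= 0 || missing_proportion >= 1)
    stop("missing_proportion must lie in (0, 1)", call. = FALSE)
  m <- if (missing_proportion <= 0.25) 10L else 20L
  while (missing_proportion / m >= loe_max) m <- m + 10L
  structure(m, loss_of_efficiency = missing_proportion / m)
}

# Bayesian linear-regression parameter draw (normal/inverse-chi-square),
# as used by proper PMM: returns the least-squares fit and one posterior draw
draw_lm <- function(X, y) {
  qrx <- qr(X)
  p <- ncol(X)
  n <- length(y)
  if (qrx$rank < p)
    stop("singular imputation design; drop collinear predictors", call. = FALSE)
  if (n <= p)
    stop("too few observed cases for the imputation model", call. = FALSE)
  beta_hat <- qr.coef(qrx, y)
  res <- y - X %*% beta_hat
  df <- n - p
  sigma2_star <- sum(res^2) / stats::rchisq(1L, df)
  R <- qr.R(qrx)
  # V = (X'X)^-1 = R^-1 R^-T ; beta* = beta_hat + chol factor %*% z * sigma*
  Rinv <- backsolve(R, diag(p))
  beta_star <- beta_hat + sqrt(sigma2_star) * (Rinv %*% stats::rnorm(p))
  list(beta_hat = beta_hat, beta_star = beta_star)
}

# type-1 predictive mean matching of one variable within one stratum;
# donors located through a sorted window around each predicted value
pmm_impute_var <- function(X_obs, y_obs, X_mis, knn) {
  fit <- draw_lm(X_obs, y_obs)
  eta_obs <- drop(X_obs %*% fit$beta_hat)
  eta_mis <- drop(X_mis %*% fit$beta_star)
  ord <- order(eta_obs)
  eo <- eta_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(eo)
  pos <- findInterval(eta_mis, eo)
  n_mis <- length(eta_mis)
  out <- numeric(n_mis)
  pick <- sample.int(knn, n_mis, replace = TRUE)
  for (i in seq_len(n_mis)) {
    # the knn nearest sorted predictions lie within this window
    lo <- max(1L, pos[i] - knn + 1L)
    hi <- min(n_obs, pos[i] + knn)
    win <- lo:hi
    nearest <- win[order(abs(eo[win] - eta_mis[i]))[seq_len(knn)]]
    out[i] <- yo[nearest[pick[i]]]
  }
  out
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Imputes missing follow-up costs and utilities with type-1 predictive mean
#' matching: within each arm stratum and for each incomplete variable, a
#' linear imputation model is fitted on the observed cases (predictors: age,
#' gender, baseline cost and utility, and the other follow-up columns), its
#' parameters are drawn from their approximate posterior, and each missing
#' case receives the observed value of one of its \code{knn} nearest donors
#' by predicted mean. A monotone pattern is completed in one sweep in visit
#' order (wave 1 to wave 4, cost then utility); otherwise the chain iterates
#' \code{n_chain_iterations} times.
#'
#' @param trial a trial table with missing follow-up values.
#' @param config an \code{\link{imputation_config}}.
#' @return object of class \code{completed_set}: a list of \code{config$m}
#'   completed trials, with the configuration attached as an attribute.
#' @examples
#' tr <- generate_complete_trial(gen_params(n_subjects = 200), seed = 1)
#' spec <- missing_spec(beta0 = -2, beta5 = log(2))
#' inc <- impose_dropout(tr, spec, seed = 2)
#' imp <- mice_pmm(inc, imputation_config(m = 2, seed = 3))
#' length(imp)
#' @export
mice_pmm <- function(trial, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  nw <- n_waves(trial)
  fu_cols <- followup_columns(trial)
  base_cols <- c("age", "gender", "cT0", "uT0")
  strata <- if (config$stratify_by_arm) sort(unique(trial$trt)) else NA
  monotone <- missing_summary(trial)$monotone

  sets <- vector("list", config$m)
  for (k in seq_len(config$m)) {
    filled <- trial
    for (a in strata) {
      rows <- if (config$stratify_by_arm) which(trial$trt == a)
              else seq_len(nrow(trial))
      sub <- trial[rows, , drop = FALSE]
      sub_filled <- if (monotone) {
        impute_monotone(sub, base_cols, nw, config)
      } else {
        impute_chained(sub, base_cols, fu_cols, config)
      }
      filled[rows, fu_cols] <- sub_filled[, fu_cols]
    }
    sets[[k]] <- filled
  }
  structure(sets, class = "completed_set", config = config,
            monotone = monotone)
}

# one ordered sweep; valid (and proper) under monotone dropout
impute_monotone <- function(sub, base_cols, nw, config) {
  done <- base_cols
  for (j in seq_len(nw)) {
    for (col in c(paste0("cT", j), paste0("uT", j))) {
      y <- sub[[col]]
      mis <- is.na(y)
      if (any(mis)) {
        X <- cbind(1, as.matrix(sub[done]))
        n_obs <- sum(!mis)
        if (n_obs < config$knn)
          stop(sprintf("not enough donors for %s (%d observed, knn=%d)",
                       col, n_obs, config$knn), call. = FALSE)
        sub[[col]][mis] <- pmm_impute_var(X[!mis, , drop = FALSE], y[!mis],
                                          X[mis, , drop = FALSE], config$knn)
      }
      done <- c(done, col)
    }
  }
  sub
}

# full chained-equations loop for arbitrary (non-monotone) patterns
impute_chained <- function(sub, base_cols, fu_cols, config) {
  miss_idx <- lapply(fu_cols, function(col) which(is.na(sub[[col]])))
  names(miss_idx) <- fu_cols
  # initialize by random draws from the observed values
  for (col in fu_cols) {
    mis <- miss_idx[[col]]
    obs <- sub[[col]][!is.na(sub[[col]])]
    if (length(obs) < config$knn)
      stop(sprintf("not enough donors for %s (%d observed, knn=%d)",
                   col, length(obs), config$knn), call. = FALSE)
    if (length(mis)) sub[[col]][mis] <- sample(obs, length(mis), replace = TRUE)
  }
  for (it in seq_len(config$n_chain_iterations)) {
    for (col in fu_cols) {
      mis <- miss_idx[[col]]
      if (!length(mis)) next
      preds <- c(base_cols, setdiff(fu_cols, col))
      X <- cbind(1, as.matrix(sub[preds]))
      y_true <- sub[[col]]
      obs <- setdiff(seq_len(nrow(sub)), mis)
      sub[[col]][mis] <- pmm_impute_var(X[obs, , drop = FALSE], y_true[obs],
                                        X[mis, , drop = FALSE], config$knn)
    }
  }
  sub
}

#' @export
print.completed_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Multiply imputed set: m = %d completed trials (knn = %d, %s, %s pattern)\n",
              cfg$m, cfg$knn,
              if (cfg$stratify_by_arm) "arm-stratified" else "pooled arms",
              if (isTRUE(attr(x, "monotone"))) "monotone" else "non-monotone"))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus \eqn{(1 + 1/m)}
#' times the between-imputation variance. Confidence intervals use the
#' Barnard-Rubin small-sample degrees of freedom when a complete-data df is
#' supplied, and a normal reference otherwise.
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param within_variances per-imputation squared standard errors.
#' @param df_com complete-data degrees of freedom (Inf for normal CI).
#' @param level confidence level.
#' @return list with \code{estimate}, \code{W}, \code{B}, \code{T},
#'   \code{df}, \code{ci}.
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))
#' @export
rubin_pool <- function(estimates, within_variances, df_com = Inf,
                       level = 0.95) {
  m <- length(estimates)
  if (m < 2L || length(within_variances) != m)
    stop("need at least two imputations with matching variances", call. = FALSE)
  if (any(within_variances < 0))
    stop("within-imputation variances must be nonnegative", call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(within_variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (Tv > 0 && B > 0) {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- Inf
  }
  tq <- stats::qt(1 - (1 - level) / 2, df)
  ci <- qbar + c(-1, 1) * tq * sqrt(Tv)
  list(estimate = qbar, W = W, B = B, T = Tv, df = df, ci = ci)
}
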