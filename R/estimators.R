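#' Reshape a wide trial to long format
#'
#' One row per subject and follow-up wave, with baseline values carried
#' along as covariates. Rows whose outcome is missing are retained with an
#' \code{NA} marker, so the long format is losslessly invertible via
#' \code{\link{reshape_wide}}.
#'
#' @param trial a wide trial table.
#' @return long \code{data.frame} with columns \code{id, trt, age, gender,
#'   cT0, uT0, wave, cost, utility}; \code{wave} is a factor.
#' @export
reshape_long <- function(trial) {
  needed <- c("id", "trt", "age", "gender", "cT0", "uT0")
  if (!all(needed %in% names(trial)))
    stop("trial lacks required columns: ",
         paste(setdiff(needed, names(trial)), collapse = ", "), call. = FALSE)
  nw <- n_waves(trial)
  n <- nrow(trial)
  long <- data.frame(
    id = rep(trial$id, nw),
    trt = rep(trial$trt, nw),
    age = rep(trial$age, nw),
    gender = rep(trial$gender, nw),
    cT0 = rep(trial$cT0, nw),
    uT0 = rep(trial$uT0, nw),
    wave = factor(rep(seq_len(nw), each = n), levels = seq_len(nw)),
    cost = unlist(trial[paste0("cT", seq_len(nw))], use.names = FALSE),
    utility = unlist(trial[paste0("uT", seq_len(nw))], use.names = FALSE)
  )
  long
}

#' Reshape a long trial back to wide format
#'
#' @param long a table produced by \code{\link{reshape_long}}.
#' @return the wide trial table.
#' @export
reshape_wide <- function(long) {
  waves <- sort(unique(as.integer(as.character(long$wave))))
  first <- long[!duplicated(long$id), c("id", "trt", "age", "gender", "cT0", "uT0")]
  first <- first[order(first$id), ]
  out <- first
  for (j in waves) {
    sub <- long[long$wave == j, ]
    sub <- sub[match(out$id, sub$id), ]
    out[[paste0("cT", j)]] <- sub$cost
    out[[paste0("uT", j)]] <- sub$utility
  }
  nw <- length(waves)
  out <- out[c("id", "trt", "age", "gender", paste0("cT", 0:nw), paste0("uT", 0:nw))]
  rownames(out) <- NULL
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Longitudinal linear mixed model for one outcome
#'
#' Fits a random-intercept mixed model by full maximum likelihood with
#' categorical wave effects (no global intercept) and wave interactions with
#' arm, baseline outcome, age and gender. Rows with a missing outcome are
#' dropped, so estimation uses the observed-data likelihood (valid under
#' MAR). The per-wave adjusted arm differences are the wave-by-arm
#' interaction coefficients; their covariance comes from the fixed-effect
#' covariance matrix.
#'
#' @param long a long table from \code{\link{reshape_long}}.
#' @param outcome \code{"cost"} or \code{"utility"}.
#' @return object of class \code{llm_fit}: per-wave contrasts \code{d} with
#'   covariance \code{vcov_d}, variance components \code{sigma2_omega} and
#'   \code{sigma2_eps}, the full fixed-effect vector, and a convergence
#'   flag.
#' @export
fit_llm_outcome <- function(long, outcome = c("cost", "utility")) {
  outcome <- match.arg(outcome)
  base <- if (outcome == "cost") "cT0" else "uT0"
  dat <- long[!is.na(long[[outcome]]), ]
  if (length(unique(dat$wave)) < 2L)
    stop("need observed data in at least two waves", call. = FALSE)
  fml <- stats::as.formula(paste0(
    outcome, " ~ 0 + wave + wave:trt + wave:", base,
    " + wave:age + wave:gender + (1 | id)"))
  converged <- TRUE
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(fml, data = dat, REML = FALSE),
             error = function(e) {
               converged <<- FALSE; msgs <<- conditionMessage(e); NULL
             }),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (is.null(fit))
    return(structure(list(d = NULL, vcov_d = NULL, converged = FALSE,
                          messages = msgs), class = "llm_fit"))
  if (!is.null(fit@optinfo$conv$lme4$messages)) {
    # boundary fits (sigma2_omega = 0) are allowed; true failures are not
    bad <- grepl("failed to converge", fit@optinfo$conv$lme4$messages)
    if (any(bad)) converged <- FALSE
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  waves <- levels(dat$wave)
  dn <- paste0("wave", waves, ":trt")
  vc <- lme4::VarCorr(fit)
  structure(list(
    d = unname(beta[dn]),
    vcov_d = unname(V[dn, dn, drop = FALSE]),
    coefficients = beta,
    sigma2_omega = as.numeric(vc$id[1]),
    sigma2_eps = attr(vc, "sc")^2,
    n_rows = nrow(dat),
    converged = converged,
    messages = msgs
  ), class = "llm_fit")
}

#' @export
print.llm_fit <- function(x, ...) {
  cat("Random-intercept mixed model (ML)\n")
  if (!x$converged) cat("  ** did not converge **\n")
  if (!is.null(x$d)) {
    cat("  per-wave adjusted arm differences:",
        paste(sprintf("%.4g", x$d), collapse = ", "), "\n")
    cat(sprintf("  sigma2_omega = %.4g, sigma2_eps = %.4g\n",
                x$sigma2_omega, x$sigma2_eps))
  }
  invisible(x)
}

#' Total cost and QALY differences from two mixed-model fits
#'
#' The total cost difference sums the per-wave cost contrasts; the QALY
#' difference applies area-under-the-curve weights to the per-wave utility
#' contrasts. Rectangle weights (each follow-up wave covers an equal share
#' of one year) make four per-wave utility differences of 0.04 integrate to
#' a 0.04 QALY difference; the trapezoid alternative (which halves the first
#' wave's weight and adds a baseline anchor of zero difference) is available
#' as an option. Variances are the corresponding quadratic forms in the
#' contrast covariance matrices.
#'
#' @param cost_fit,utility_fit \code{llm_fit} objects.
#' @param auc \code{"rectangle"} (default) or \code{"trapezoid"}.
#' @return list with \code{dc}, \code{var_dc}, \code{dq}, \code{var_dq} and
#'   the weight vectors used.
#' @export
llm_totals <- function(cost_fit, utility_fit, auc = c("rectangle", "trapezoid")) {
  auc <- match.arg(auc)
  if (is.null(cost_fit$vcov_d) || is.null(utility_fit$vcov_d))
    stop("contrast covariance unavailable (non-converged fit?)", call. = FALSE)
  nw <- length(cost_fit$d)
  w_cost <- rep(1, nw)
  w_util <- auc_weights(nw, auc)
  dc <- sum(w_cost * cost_fit$d)
  var_dc <- drop(t(w_cost) %*% cost_fit$vcov_d %*% w_cost)
  dq <- sum(w_util * utility_fit$d)
  var_dq <- drop(t(w_util) %*% utility_fit$vcov_d %*% w_util)
  list(dc = dc, var_dc = var_dc, dq = dq, var_dq = var_dq,
       w_cost = w_cost, w_util = w_util)
}

# AUC weights on the follow-up waves for one year of follow-up; the
# trapezoid version assigns the baseline anchor half of the first interval
# (its arm difference is zero by design, so only follow-up weights matter)
auc_weights <- function(nw, auc) {
  if (auc == "rectangle") rep(1 / nw, nw)
  else c(rep(1 / nw, nw - 1L), 1 / (2 * nw))
}

#' Per-subject total costs and QALYs
#'
#' Total costs sum the follow-up waves; QALYs apply the area-under-the-curve
#' weights of \code{\link{llm_totals}} to the follow-up utilities.
#'
#' @param trial a trial table with no missing values (impute or filter
#'   first).
#' @param auc \code{"rectangle"} or \code{"trapezoid"}.
#' @return \code{data.frame} with \code{id, trt, age, gender, cT0, uT0,
#'   total_cost, qaly}.
#' @export
aggregate_totals <- function(trial, auc = c("rectangle", "trapezoid")) {
  auc <- match.arg(auc)
  nw <- n_waves(trial)
  cmat <- as.matrix(trial[paste0("cT", seq_len(nw))])
  umat <- as.matrix(trial[paste0("uT", seq_len(nw))])
  if (anyNA(cmat) || anyNA(umat))
    stop("missing follow-up values: impute or drop incomplete subjects first",
         call. = FALSE)
  w <- auc_weights(nw, auc)
  data.frame(id = trial$id, trt = trial$trt, age = trial$age,
             gender = trial$gender, cT0 = trial$cT0, uT0 = trial$uT0,
             total_cost = rowSums(cmat),
             qaly = drop(umat %*% w))
}

#' Seemingly unrelated regressions for total costs and QALYs
#'
#' Two-equation system (total costs on arm, baseline costs, age, gender;
#' QALYs on arm, baseline utility, age, gender) estimated by two-step
#' feasible generalized least squares with an unrestricted cross-equation
#' residual covariance. With identical regressor matrices in both equations
#' the FGLS point estimates coincide exactly with per-equation least
#' squares; with different baseline covariates (the default) the joint fit
#' supplies the covariance between the cost and QALY arm coefficients.
#'
#' @param totals per-subject totals from \code{\link{aggregate_totals}}.
#' @return object of class \code{sur_fit}: arm coefficients \code{dc},
#'   \code{dq} with variances and covariance, residual covariance matrix
#'   \code{sigma}, all coefficients, their joint covariance, and \code{n}.
#' @export
fit_sur <- function(totals) {
  if (nrow(totals) < 10L) stop("need at least 10 rows", call. = FALSE)
  if (anyNA(totals)) stop("totals must be complete", call. = FALSE)
  Xc <- cbind(1, totals$trt, totals$cT0, totals$age, totals$gender)
  Xq <- cbind(1, totals$trt, totals$uT0, totals$age, totals$gender)
  colnames(Xc) <- c("(Intercept)", "trt", "cT0", "age", "gender")
  colnames(Xq) <- c("(Intercept)", "trt", "uT0", "age", "gender")
  yc <- totals$total_cost
  yq <- totals$qaly
  n <- nrow(totals)
  bc0 <- qr.coef(qr(Xc), yc)
  bq0 <- qr.coef(qr(Xq), yq)
  if (anyNA(bc0) || anyNA(bq0)) stop("singular design", call. = FALSE)
  E <- cbind(yc - Xc %*% bc0, yq - Xq %*% bq0)
  S <- crossprod(E) / n
  Sinv <- solve(S)
  # block form of (X' (Sinv x I) X) beta = X' (Sinv x I) y
  A <- rbind(
    cbind(Sinv[1, 1] * crossprod(Xc), Sinv[1, 2] * crossprod(Xc, Xq)),
    cbind(Sinv[2, 1] * crossprod(Xq, Xc), Sinv[2, 2] * crossprod(Xq)))
  b <- c(Sinv[1, 1] * crossprod(Xc, yc) + Sinv[1, 2] * crossprod(Xc, yq),
         Sinv[2, 1] * crossprod(Xq, yc) + Sinv[2, 2] * crossprod(Xq, yq))
  # Jacobi-scale the normal equations: costs and QALYs live on scales many
  # orders of magnitude apart, which would otherwise wreck the conditioning
  d <- sqrt(diag(A))
  As <- A / tcrossprod(d)
  V <- solve(As) / tcrossprod(d)
  beta <- drop(V %*% b)
  pc <- ncol(Xc)
  names(beta) <- c(paste0("cost.", colnames(Xc)), paste0("qaly.", colnames(Xq)))
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(
    dc = beta[["cost.trt"]], dq = beta[["qaly.trt"]],
    var_dc = V["cost.trt", "cost.trt"], var_dq = V["qaly.trt", "qaly.trt"],
    cov_dcdq = V["cost.trt", "qaly.trt"],
    coefficients = beta, vcov = V, sigma = S, n = n
  ), class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat("Seemingly unrelated regressions (two-step FGLS)\n")
  cat(sprintf("  dC = %.2f (SE %.2f), dQ = %.4f (SE %.4f), Cov = %.4g, n = %d\n",
              x$dc, sqrt(x$var_dc), x$dq, sqrt(x$var_dq), x$cov_dcdq, x$n))
  cat(sprintf("  residual correlation = %.3f\n",
              x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2])))
  invisible(x)
}

#' The six analysis strategies
#' @return character vector of strategy labels.
#' @export
strategies <- function() {
  c("LLM", "M-LLM", "MI-LLM", "SUR-CCA", "M-SUR", "MI-SUR")
}

make_estimate <- function(strategy, dc, var_dc, dq, var_dq, cov_dcdq,
                          cov_available, ci_dc, ci_dq, n, m = NA_integer_,
                          converged = TRUE) {
  structure(list(strategy = strategy, dc = dc, var_dc = var_dc,
                 dq = dq, var_dq = var_dq, cov_dcdq = cov_dcdq,
                 cov_available = cov_available, ci_dc = ci_dc, ci_dq = ci_dq,
                 n = n, m = m, converged = converged),
            class = "strategy_estimate")
}

#' @export
print.strategy_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (n = %d%s)\n", x$strategy, x$n,
              if (!is.na(x$m)) sprintf(", m = %d", x$m) else ""))
  cat(sprintf("  dCosts = %.2f EUR  (95%% CI %.2f to %.2f)\n",
              x$dc, x$ci_dc[1], x$ci_dc[2]))
  cat(sprintf("  dQALY  = %.4f      (95%% CI %.4f to %.4f)\n",
              x$dq, x$ci_dq[1], x$ci_dq[2]))
  cat(sprintf("  Cov(dC, dQ) = %s\n",
              if (x$cov_available) sprintf("%.4g", x$cov_dcdq)
              else "unavailable (set to 0)"))
  if (!x$converged) cat("  ** component fit did not converge **\n")
  invisible(x)
}

z_ci <- function(est, var, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est + c(-1, 1) * z * sqrt(var)
}

#' Analyse an incomplete trial with one strategy
#'
#' Dispatches the six strategies: mixed models on the available data
#' (\code{LLM}), after unconditional mean imputation (\code{M-LLM}) or on
#' multiply imputed data pooled by Rubin's rules (\code{MI-LLM}); and the
#' two-equation total-cost/QALY model on complete cases (\code{SUR-CCA}),
#' after mean imputation (\code{M-SUR}) or on multiply imputed data
#' (\code{MI-SUR}). The covariance between the cost and QALY differences is
#' taken from the joint fit for the SUR family (Rubin-pooled for
#' \code{MI-SUR}); the mixed-model family fits costs and utilities in
#' separate univariate models, so its covariance is unavailable and recorded
#' as 0 with \code{cov_available = FALSE}.
#'
#' @param trial an incomplete (or complete) trial table.
#' @param strategy one of \code{\link{strategies}()}.
#' @param impute_config \code{\link{imputation_config}} for the MI
#'   strategies.
#' @param auc area-under-the-curve convention for QALYs.
#' @param level confidence level.
#' @return a \code{strategy_estimate}.
#' @export
run_strategy <- function(trial, strategy, impute_config = imputation_config(),
                         auc = "rectangle", level = 0.95) {
  if (!strategy %in% strategies())
    stop("unknown strategy: ", strategy, call. = FALSE)
  nw <- n_waves(trial)

  if (strategy %in% c("LLM", "M-LLM")) {
    use <- if (strategy == "M-LLM") mean_impute(trial) else trial
    long <- reshape_long(use)
    fc <- fit_llm_outcome(long, "cost")
    fu <- fit_llm_outcome(long, "utility")
    if (!fc$converged || !fu$converged || is.null(fc$d) || is.null(fu$d))
      return(make_estimate(strategy, NA_real_, NA_real_, NA_real_, NA_real_,
                           0, FALSE, c(NA, NA), c(NA, NA), nrow(trial),
                           converged = FALSE))
    tot <- llm_totals(fc, fu, auc)
    return(make_estimate(strategy, tot$dc, tot$var_dc, tot$dq, tot$var_dq,
                         0, FALSE,
                         z_ci(tot$dc, tot$var_dc, level),
                         z_ci(tot$dq, tot$var_dq, level), nrow(trial)))
  }

  if (strategy == "MI-LLM") {
    sets <- mice_pmm(trial, impute_config)
    m <- length(sets)
    dcs <- dqs <- vcs <- vqs <- numeric(m)
    ok <- TRUE
    for (k in seq_len(m)) {
      long <- reshape_long(sets[[k]])
      fc <- fit_llm_outcome(long, "cost")
      fu <- fit_llm_outcome(long, "utility")
      if (!fc$converged || !fu$converged) { ok <- FALSE; break }
      tot <- llm_totals(fc, fu, auc)
      dcs[k] <- tot$dc; vcs[k] <- tot$var_dc
      dqs[k] <- tot$dq; vqs[k] <- tot$var_dq
    }
    if (!ok)
      return(make_estimate(strategy, NA_real_, NA_real_, NA_real_, NA_real_,
                           0, FALSE, c(NA, NA), c(NA, NA), nrow(trial), m,
                           converged = FALSE))
    df_com <- nw * nrow(trial) - 5L * nw
    pc <- rubin_pool(dcs, vcs, df_com = df_com, level = level)
    pq <- rubin_pool(dqs, vqs, df_com = df_com, level = level)
    return(make_estimate(strategy, pc$estimate, pc$T, pq$estimate, pq$T,
                         0, FALSE, pc$ci, pq$ci, nrow(trial), m))
  }

  if (strategy %in% c("SUR-CCA", "M-SUR")) {
    use <- switch(strategy,
                  "SUR-CCA" = trial[stats::complete.cases(trial), , drop = FALSE],
                  "M-SUR" = mean_impute(trial))
    fit <- fit_sur(aggregate_totals(use, auc))
    return(make_estimate(strategy, fit$dc, fit$var_dc, fit$dq, fit$var_dq,
                         fit$cov_dcdq, TRUE,
                         z_ci(fit$dc, fit$var_dc, level),
                         z_ci(fit$dq, fit$var_dq, level), fit$n))
  }

  # MI-SUR
  sets <- mice_pmm(trial, impute_config)
  m <- length(sets)
  dcs <- dqs <- vcs <- vqs <- cvs <- numeric(m)
  for (k in seq_len(m)) {
    fit <- fit_sur(aggregate_totals(sets[[k]], auc))
    dcs[k] <- fit$dc; vcs[k] <- fit$var_dc
    dqs[k] <- fit$dq; vqs[k] <- fit$var_dq
    cvs[k] <- fit$cov_dcdq
  }
  df_com <- nrow(trial) - 5L
  pc <- rubin_pool(dcs, vcs, df_com = df_com, level = level)
  pq <- rubin_pool(dqs, vqs, df_com = df_com, level = level)
  cov_pooled <- mean(cvs) + (1 + 1 / m) * stats::cov(dcs, dqs)
  make_estimate("MI-SUR", pc$estimate, pc$T, pq$estimate, pq$T,
                cov_pooled, TRUE, pc$ci, pq$ci, nrow(trial), m)
}
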