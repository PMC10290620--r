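#' Empirical bias with Monte Carlo standard error
#'
#' @param estimates per-replication point estimates.
#' @param theta true value of the estimand.
#' @return list with \code{eb} and \code{mcse} (= SD of the estimates over
#'   the square root of the number of replications).
#' @examples
#' empirical_bias(c(248, 252, 250, 254), 250)
#' @export
empirical_bias <- function(estimates, theta) {
  estimates <- estimates[is.finite(estimates)]
  n <- length(estimates)
  if (n < 2L) stop("need at least two estimates", call. = FALSE)
  list(eb = mean(estimates) - theta,
       mcse = stats::sd(estimates) / sqrt(n))
}

#' Root-mean-squared error with Monte Carlo standard error
#'
#' RMSE is the square root of the mean squared deviation from the true
#' value. Its MCSE is obtained by the delta method from the MCSE of the
#' mean squared error: \code{MCSE(RMSE) = MCSE(MSE) / (2 RMSE)}.
#'
#' @inheritParams empirical_bias
#' @return list with \code{rmse} and \code{mcse}.
#' @export
rmse <- function(estimates, theta) {
  estimates <- estimates[is.finite(estimates)]
  n <- length(estimates)
  if (n < 2L) stop("need at least two estimates", call. = FALSE)
  sq <- (estimates - theta)^2
  mse <- mean(sq)
  r <- sqrt(mse)
  mcse <- if (r > 0) stats::sd(sq) / sqrt(n) / (2 * r) else 0
  list(rmse = r, mcse = mcse)
}

#' Coverage rate with Monte Carlo standard error
#'
#' Proportion of replications whose confidence interval contains the true
#' value; the MCSE is the binomial standard error
#' \code{sqrt(CR (1 - CR) / n)}.
#'
#' @param ci_lowers,ci_uppers per-replication interval bounds.
#' @inheritParams empirical_bias
#' @return list with \code{cr} and \code{mcse}, both on the proportion
#'   scale.
#' @examples
#' # 0.948 observed over 2000 replications -> MCSE 0.00496 (0.496 points)
#' coverage(rep(c(0, 1), c(1896, 104)), rep(2, 2000), 1)
#' @export
coverage <- function(ci_lowers, ci_uppers, theta) {
  if (length(ci_lowers) != length(ci_uppers))
    stop("bound vectors must have equal length", call. = FALSE)
  keep <- is.finite(ci_lowers) & is.finite(ci_uppers)
  lo <- ci_lowers[keep]; up <- ci_uppers[keep]
  if (any(lo > up)) stop("lower bound exceeds upper bound", call. = FALSE)
  n <- length(lo)
  if (n < 1L) stop("no usable intervals", call. = FALSE)
  cr <- mean(lo <= theta & theta <= up)
  list(cr = cr, mcse = sqrt(cr * (1 - cr) / n))
}

#' Replications needed for a target coverage precision
#'
#' Number of Monte Carlo replications so that the standard error of an
#' expected coverage proportion does not exceed \code{max_mcse} percentage
#' points: \code{p (1 - p) / se^2}, rounded up.
#'
#' @param expected_coverage anticipated coverage proportion, in (0, 1).
#' @param max_mcse maximal Monte Carlo standard error, in percentage
#'   points.
#' @return integer number of replications.
#' @examples
#' required_nsim(0.95, 0.5)  # 1900
#' @export
required_nsim <- function(expected_coverage, max_mcse) {
  if (expected_coverage <= 0 || expected_coverage >= 1)
    stop("expected_coverage must lie in (0, 1)", call. = FALSE)
  if (max_mcse <= 0) stop("max_mcse must be positive", call. = FALSE)
  se <- max_mcse / 100
  v <- expected_coverage * (1 - expected_coverage) / se^2
  # guard the ceiling against floating-point overshoot (e.g. 1900 + 2e-13)
  as.integer(ceiling(v - 1e-8))
}

#' Performance table over replications
#'
#' Builds one row per scenario, strategy and outcome with empirical bias,
#' RMSE and coverage rate, each with its Monte Carlo standard error.
#' Coverage is flagged as poor when it differs from the nominal 0.95 by more
#' than 1.96 times its own MCSE. Every row is checked against the algebraic
#' identity \eqn{RMSE^2 = EB^2 + (n-1)/n \times Var}.
#'
#' @param results \code{data.frame} of per-replication estimates with
#'   columns \code{scenario, strategy, dc, dq, ci_dc_lo, ci_dc_hi,
#'   ci_dq_lo, ci_dq_hi, converged}.
#' @param truths list with \code{theta_cost} and \code{theta_qaly}
#'   (\code{\link{true_effects}}).
#' @param nominal nominal coverage level.
#' @return \code{data.frame} with one row per scenario x strategy x
#'   outcome.
#' @export
performance_table <- function(results, truths, nominal = 0.95) {
  stopifnot(all(c("scenario", "strategy", "dc", "dq") %in% names(results)))
  cells <- unique(results[c("scenario", "strategy")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- results$scenario == cells$scenario[i] &
      results$strategy == cells$strategy[i]
    sub <- results[sel, ]
    ok <- sub$converged & is.finite(sub$dc) & is.finite(sub$dq)
    sub <- sub[ok, ]
    n_excluded <- sum(!ok)
    if (nrow(sub) < 2L) {
      warning(sprintf("cell %s/%s has fewer than 2 usable replications",
                      cells$scenario[i], cells$strategy[i]))
      next
    }
    for (outc in c("cost", "QALY")) {
      theta <- if (outc == "cost") truths$theta_cost else truths$theta_qaly
      est <- if (outc == "cost") sub$dc else sub$dq
      lo <- if (outc == "cost") sub$ci_dc_lo else sub$ci_dq_lo
      hi <- if (outc == "cost") sub$ci_dc_hi else sub$ci_dq_hi
      eb <- empirical_bias(est, theta)
      rm <- rmse(est, theta)
      cv <- coverage(lo, hi, theta)
      n <- length(est)
      # RMSE^2 = EB^2 + (n-1)/n * Var: consistency check on every build
      lhs <- rm$rmse^2
      rhs <- eb$eb^2 + (n - 1) / n * stats::var(est)
      if (abs(lhs - rhs) > 1e-8 * max(1, lhs))
        stop("internal error: RMSE decomposition identity violated",
             call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = cells$scenario[i], strategy = cells$strategy[i],
        outcome = outc,
        eb = eb$eb, mcse_eb = eb$mcse,
        rmse = rm$rmse, mcse_rmse = rm$mcse,
        cr = cv$cr, mcse_cr = cv$mcse,
        n_used = n, n_excluded = n_excluded,
        poor_coverage = abs(cv$cr - nominal) > 1.96 * cv$mcse,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
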