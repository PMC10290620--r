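#' Probability that the incremental net benefit is positive
#'
#' The incremental net benefit at willingness-to-pay \eqn{\lambda} is
#' \eqn{INB = \lambda \Delta_q - \Delta_c}. Under a normal approximation,
#' \deqn{Pr(INB > 0 | \lambda) = \Phi\left(\frac{\lambda \Delta_q -
#'   \Delta_c}{\sqrt{\lambda^2 Var(\Delta_q) + Var(\Delta_c) -
#'   2 \lambda Cov(\Delta_q, \Delta_c)}}\right).}
#' At \eqn{\lambda = 0} this reduces to \eqn{\Phi(-\Delta_c /
#' SE(\Delta_c))} and depends only on the cost difference.
#'
#' @param dq,dc differences in QALYs and total costs (intervention minus
#'   control).
#' @param var_q,var_c variances of the two differences.
#' @param cov_qc their covariance.
#' @param lambda willingness-to-pay threshold (currency per QALY).
#' @return probability in (0, 1).
#' @examples
#' inb_probability(dq = -0.002, dc = -711, var_q = 1e-4,
#'                 var_c = 491.3^2, cov_qc = 0, lambda = 0)
#' @export
inb_probability <- function(dq, dc, var_q, var_c, cov_qc = 0, lambda) {
  if (var_q < 0 || var_c < 0)
    stop("variances must be nonnegative", call. = FALSE)
  if (abs(cov_qc) > sqrt(var_q * var_c) + 1e-12)
    stop("covariance inconsistent with the variances", call. = FALSE)
  v <- lambda^2 * var_q + var_c - 2 * lambda * cov_qc
  if (v <= 0)
    stop("degenerate INB distribution (zero variance)", call. = FALSE)
  stats::pnorm((lambda * dq - dc) / sqrt(v))
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates \code{\link{inb_probability}} on a grid of willingness-to-pay
#' values for one strategy estimate, and reports the probabilities at the
#' conventional thresholds of 10,000, 20,000 and 50,000 per QALY.
#'
#' @param est a \code{strategy_estimate} (from \code{\link{run_strategy}})
#'   or any list with \code{dq, dc, var_dq, var_dc, cov_dcdq}.
#' @param lambdas willingness-to-pay grid.
#' @param thresholds reporting thresholds.
#' @return \code{data.frame} with columns \code{lambda} and
#'   \code{probability}; the threshold probabilities are attached as the
#'   \code{"thresholds"} attribute.
#' @export
ceac_curve <- function(est, lambdas = seq(0, 80000, by = 1000),
                       thresholds = c(10000, 20000, 50000)) {
  cov_qc <- if (isTRUE(est$cov_available)) est$cov_dcdq else 0
  pr <- vapply(lambdas, function(l)
    inb_probability(est$dq, est$dc, est$var_dq, est$var_dc, cov_qc, l),
    numeric(1))
  thr <- vapply(thresholds, function(l)
    inb_probability(est$dq, est$dc, est$var_dq, est$var_dc, cov_qc, l),
    numeric(1))
  structure(data.frame(lambda = lambdas, probability = pr),
            thresholds = stats::setNames(thr, thresholds))
}

#' Incremental cost-effectiveness ratio
#'
#' @param dc,dq cost and QALY differences.
#' @return the ratio \code{dc / dq} with a \code{quadrant} attribute:
#'   \code{"dominant"} (cheaper and more effective), \code{"dominated"}
#'   (costlier and less effective), or \code{"trade-off"}.
#' @examples
#' icer(250, 0.04)
#' @export
icer <- function(dc, dq) {
  if (dq == 0) stop("ICER undefined for a zero QALY difference", call. = FALSE)
  quadrant <- if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "trade-off"
  structure(dc / dq, quadrant = quadrant)
}

#' Standard error from a printed confidence interval
#'
#' Recovers the standard error behind a symmetric normal-based interval:
#' \code{(upper - lower) / (2 z)}. Used to reconstruct published
#' incremental-net-benefit probabilities from reported point estimates and
#' 95 percent confidence intervals.
#'
#' @param lower,upper interval bounds.
#' @param level confidence level of the interval.
#' @return the implied standard error.
#' @examples
#' se_from_ci(-1674, 252)  # 491.3
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (upper < lower) stop("upper must be at least lower", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  (upper - lower) / (2 * z)
}
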