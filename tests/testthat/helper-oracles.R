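# Independent brute-force oracles used to validate the estimators.

# Random-intercept Gaussian ML by direct numerical maximization of the
# closed-form marginal likelihood (Woodbury identities per subject),
# independent of lme4. Returns the GLS fixed effects at the ML variance
# components.
oracle_llm_ml <- function(X, y, id) {
  ids <- unique(id)
  split_idx <- split(seq_along(y), id)
  neg_loglik_beta <- function(par) {
    s2e <- exp(par[1]); s2w <- exp(par[2])
    # GLS accumulation
    A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
    ll_const <- 0
    for (idx in split_idx) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      shrink <- s2w / (s2e + ni * s2w)
      # Vi^-1 = (1/s2e) (I - shrink * J)
      xs <- colSums(Xi); ys <- sum(yi)
      A <- A + (crossprod(Xi) - shrink * tcrossprod(xs)) / s2e
      b <- b + (crossprod(Xi, yi) - shrink * xs * ys) / s2e
      ll_const <- ll_const + (ni - 1) * log(s2e) + log(s2e + ni * s2w)
    }
    beta <- solve(A, b)
    quad <- 0
    for (idx in split_idx) {
      ni <- length(idx)
      ri <- y[idx] - X[idx, , drop = FALSE] %*% beta
      shrink <- s2w / (s2e + ni * s2w)
      quad <- quad + (sum(ri^2) - shrink * sum(ri)^2) / s2e
    }
    list(nll = 0.5 * (ll_const + quad + length(y) * log(2 * pi)),
         beta = beta)
  }
  fn <- function(par) neg_loglik_beta(par)$nll
  # crude grid start, then high-precision Nelder-Mead
  v <- stats::var(y)
  best <- NULL
  for (frac in c(0.2, 0.5, 0.8)) {
    st <- log(c(v * (1 - frac), v * frac))
    op <- stats::optim(st, fn, control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || op$value < best$value) best <- op
  }
  out <- neg_loglik_beta(best$par)
  list(beta = drop(out$beta), sigma2_eps = exp(best$par[1]),
       sigma2_omega = exp(best$par[2]))
}

# model matrix matching fit_llm_outcome's parameterization
llm_model_matrix <- function(long, outcome) {
  base <- if (outcome == "cost") "cT0" else "uT0"
  dat <- long[!is.na(long[[outcome]]), ]
  fml <- stats::as.formula(paste0(
    "~ 0 + wave + wave:trt + wave:", base, " + wave:age + wave:gender"))
  list(X = stats::model.matrix(fml, dat), y = dat[[outcome]], id = dat$id,
       names = colnames(stats::model.matrix(fml, dat)))
}

# textbook two-step FGLS through the explicit kronecker-product formula
oracle_sur_kron <- function(totals) {
  Xc <- cbind(1, totals$trt, totals$cT0, totals$age, totals$gender)
  Xq <- cbind(1, totals$trt, totals$uT0, totals$age, totals$gender)
  yc <- totals$total_cost; yq <- totals$qaly
  n <- nrow(totals)
  bc <- solve(crossprod(Xc), crossprod(Xc, yc))
  bq <- solve(crossprod(Xq), crossprod(Xq, yq))
  E <- cbind(yc - Xc %*% bc, yq - Xq %*% bq)
  S <- crossprod(E) / n
  X <- rbind(cbind(Xc, matrix(0, n, ncol(Xq))),
             cbind(matrix(0, n, ncol(Xc)), Xq))
  Omega_inv <- solve(S) %x% diag(n)
  V <- solve(t(X) %*% Omega_inv %*% X)
  beta <- V %*% t(X) %*% Omega_inv %*% c(yc, yq)
  list(beta = drop(beta), vcov = V)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

default_params_small <- function(n = 200L) {
  p <- gen_params()
  p$n_subjects <- as.integer(n)
  p
}
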