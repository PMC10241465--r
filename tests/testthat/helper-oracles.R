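# Independent oracles used across tests; written from first principles,
# deliberately not calling the package's code paths.

# Closed-form BLUP for one subject: b_i = S Z' (Z S Z' + s2 I)^-1 (y - X beta)
oracle_blup <- function(t_days, y, beta, Sigma, sigma_e) {
  Z <- cbind(1, t_days)
  V <- Z %*% Sigma %*% t(Z) + diag(sigma_e^2, length(y))
  as.numeric(Sigma %*% t(Z) %*% solve(V, y - Z %*% beta))
}

# OLS by the normal equations
oracle_ols <- function(t, y) {
  X <- cbind(1, t)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Product-limit estimator by direct enumeration (events before censorings
# at tied times)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ut, surv = surv)
}

default_cohort <- function(n, seed) {
  set.seed(seed)
  simulate_cohort(pop_params(), visit_schedule(), n)
}
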