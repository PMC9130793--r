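# Independent oracles used to verify the package's estimators.

# hand-rolled OLS via explicit normal equations (no lm, no package code)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  list(intercept = beta[1], slope = beta[2], se = se,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# hand Welch-Satterthwaite computation
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force trajectory stepping: clamped piecewise-constant-rate RMR and
# trapezoid mass integration on a dense grid (no lags)
step_oracle <- function(params, schedule, growth, rmr0, m0, dt = 0.001) {
  tt <- seq(0, schedule$total_days, by = dt)
  lev <- food_level_at(schedule, pmin(tt + dt / 2, schedule$total_days))
  rmr <- numeric(length(tt))
  mass <- numeric(length(tt))
  rmr[1] <- rmr0
  mass[1] <- m0
  for (i in seq_len(length(tt) - 1)) {
    slope <- if (lev[i] == "HIGH") params$rate_up / 7 else -params$rate_down / 7
    rmr[i + 1] <- min(max(rmr[i] + slope * dt, params$rmr_min), params$rmr_max)
    g0 <- growth$c[lev[i]] + growth$d[lev[i]] * rmr[i]
    g1 <- growth$c[lev[i]] + growth$d[lev[i]] * rmr[i + 1]
    mass[i + 1] <- max(mass[i] + (g0 + g1) / 2 * dt, 0)
  }
  list(time_days = tt, rmr = rmr, mass = mass)
}

# analytic mean of a truncated Normal
truncnorm_mean_oracle <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
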