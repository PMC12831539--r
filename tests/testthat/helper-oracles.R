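# Independent oracles used across the suite. Each one is a deliberately
# naive long-form computation, kept separate from the package's own code
# paths.

# Ordinary least squares via the normal equations, solved directly.
normal_equations_fit <- function(y, baseline, age, sex, education,
                                 interval) {
  X <- cbind(1, baseline, age, sex, education, interval)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(beta = drop(beta),
       residual_sd = sqrt(sum(resid^2) / (length(y) - ncol(X))))
}

# Benjamini-Hochberg step-up, written long-form: sort, scale, cumulative
# minimum from the largest rank, map back.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Log partial likelihood of a Cox model with a single covariate and no
# tied event times, evaluated directly from its definition.
cox_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Maximizer of the partial likelihood by dense grid search with one
# refinement pass.
cox_grid_mle <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, cox_log_partial_lik, 0, time = time, event = event,
               x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, cox_log_partial_lik, 0, time = time, event = event,
                x = x)
  fine[which.max(llf)]
}

# Product-limit (Kaplan-Meier) estimator computed long-form.
km_long_form <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}
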