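# Independent oracles used to cross-check the package's estimators.

# Exhaustive pairwise concordance: every event/non-event pair, ties 1/2.
brute_force_c <- function(risks, outcomes) {
  ev <- risks[outcomes == 1]
  ne <- risks[outcomes == 0]
  total <- 0
  for (a in ev) {
    for (b in ne) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(ev) * length(ne))
}

# Newton-Raphson maximum-likelihood logistic regression (independent of
# glm's IRLS code path).
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, vcov = solve(info))
}

# Restricted log-likelihood of a random-effects meta-analysis at tau2.
reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

# Grid + golden-section maximiser of the restricted likelihood.
reml_grid_oracle <- function(yi, vi) {
  upper <- max(1e-8, 10 * var(yi))
  grid <- seq(0, upper, length.out = 2001)
  ll <- vapply(grid, reml_loglik, numeric(1), yi = yi, vi = vi)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(reml_loglik, c(lo, hi), yi = yi, vi = vi,
                  maximum = TRUE, tol = 1e-10)
  tau2 <- if (reml_loglik(0, yi, vi) >= opt$objective) 0 else opt$maximum
  w <- 1 / (vi + tau2)
  list(tau2 = tau2, mu = sum(w * yi) / sum(w), se = sqrt(1 / sum(w)))
}
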