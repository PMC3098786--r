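# Independent oracles and fixture builders shared across test files.

# Bare snapshot from explicit (time, event) pairs.
make_snapshot <- function(time, event, t = max(time) + 1) {
  structure(list(index = seq_along(time), time = as.numeric(time),
                 event = as.integer(event), t = t, n = length(time)),
            class = "survival_snapshot")
}

# Brute-force BH step-up: enumerate k from the top.
bh_reject_bruteforce <- function(p, alpha) {
  d <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (j in d:1) if (ps[j] <= j / d * alpha) { k <- j; break }
  if (k == 0L) integer(0) else sort(o[seq_len(k)])
}

# Breslow log partial likelihood for one gene, direct double loop.
cox_loglik_breslow <- function(beta, time, event, x) {
  ll <- 0
  for (j in which(event == 1)) {
    rs <- time >= time[j]
    ll <- ll + beta * x[j] - log(sum(exp(beta * x[rs])))
  }
  ll
}

# Grid + refine maximizer of the Breslow partial likelihood over
# beta in [-10, 10]; resolution well below 1e-4.
grid_cox_beta <- function(time, event, x) {
  grid <- seq(-10, 10, by = 0.01)
  ll <- vapply(grid, cox_loglik_breslow, numeric(1),
               time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(cox_loglik_breslow, c(b0 - 0.02, b0 + 0.02),
                  time = time, event = event, x = x,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# Dense-Cholesky MVN sampler with AR(1) covariance (reference for the
# sequential construction).
chol_ar1_draws <- function(d, n, rho, sigma2 = 1) {
  S <- sigma2 * rho^abs(outer(seq_len(d), seq_len(d), "-"))
  t(matrix(stats::rnorm(n * d), n, d) %*% chol(S))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
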