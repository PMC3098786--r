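test_that("degenerate snapshots give p = 1", {
  # no events at all
  sn <- make_snapshot(time = c(5, 6, 7), event = c(0, 0, 0))
  r <- fit_cox_gene(sn, c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_equal(r$status, "degenerate")
  # a single event is still below the 2-event floor
  sn1 <- make_snapshot(c(5, 6, 7), c(1, 0, 0))
  expect_equal(fit_cox_gene(sn1, c(1, 2, 3))$status, "degenerate")
  # constant covariate carries no contrast
  sn2 <- make_snapshot(1:6, rep(1L, 6))
  r2 <- fit_cox_gene(sn2, rep(2.5, 6))
  expect_equal(r2$p, 1)
  expect_equal(r2$status, "degenerate")
})

test_that("beta_hat matches the grid partial-likelihood oracle", {
  # 8-patient fixture, all events; the interleaved covariate keeps the
  # partial likelihood strictly concave with an interior maximizer
  time <- 1:8; event <- rep(1L, 8)
  x <- c(0, 1, 0, 1, 0, 1, 1, 0)
  sn <- make_snapshot(time, event)
  r <- fit_cox_gene(sn, x)
  b_oracle <- grid_cox_beta(time, event, x)
  expect_lt(abs(r$beta_hat - b_oracle), 1e-4)
  expect_equal(r$status, "ok")
  # the fully ordered covariate (all x = 0 deaths first) is separated: the
  # likelihood is monotone in beta and the fit must flag the fallback
  xs <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(fit_cox_gene(sn, xs)$status, "fallback")
  # and on a few random fixtures with censoring and ties
  set.seed(14)
  for (i in 1:5) {
    n <- 12
    tm <- sample(1:6, n, replace = TRUE)  # deliberate ties
    evn <- rbinom(n, 1, 0.8)
    if (sum(evn) < 2) evn[1:2] <- 1L
    xx <- rnorm(n)
    rr <- fit_cox_gene(make_snapshot(tm, evn), xx)
    expect_lt(abs(rr$beta_hat - grid_cox_beta(tm, evn, xx)), 1e-4)
  }
})

test_that("agreement with survival::coxph on random small datasets", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:25) {
    n <- sample(15:50, 1)
    time <- rexp(n, 1 / 10)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) event[1:2] <- 1L
    x <- rnorm(n)
    mine <- fit_cox_gene(make_snapshot(time, event), x)
    ref <- summary(survival::coxph(survival::Surv(time, event) ~ x,
                                   ties = "breslow"))$coefficients
    expect_lt(abs(mine$beta_hat - ref[1, "coef"]),
              1e-6 * max(1, abs(ref[1, "coef"])))
    expect_lt(abs(mine$p - ref[1, "Pr(>|z|)"]), 1e-6)
    expect_lt(abs(mine$se - ref[1, "se(coef)"]),
              1e-6 * ref[1, "se(coef)"])
  }
})

test_that("sign symmetry and scale equivariance", {
  set.seed(8)
  time <- rexp(30, 1 / 10); event <- rbinom(30, 1, 0.8)
  x <- rnorm(30)
  sn <- make_snapshot(time, event)
  a <- fit_cox_gene(sn, x)
  b <- fit_cox_gene(sn, -x)
  expect_equal(a$beta_hat, -b$beta_hat, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  cc <- 3.7
  d <- fit_cox_gene(sn, cc * x)
  expect_equal(d$beta_hat, a$beta_hat / cc, tolerance = 1e-7)
  expect_equal(d$p, a$p, tolerance = 1e-8)
})

test_that("separated covariates fall back to the score test", {
  # covariate perfectly ordered with uncensored survival: monotone likelihood
  time <- 1:10; event <- rep(1L, 10); x <- 1:10
  r <- fit_cox_gene(make_snapshot(time, event), x)
  expect_equal(r$status, "fallback")
  expect_true(r$p >= 0 && r$p <= 1)
  expect_lt(r$p, 0.05)  # the score test still sees strong signal
})

test_that("screen_genes is permutation-equivariant and handles edge cases", {
  set.seed(19)
  n <- 40; d <- 60
  time <- rexp(n, 1 / 10); event <- rbinom(n, 1, 0.7)
  sn <- make_snapshot(time, event)
  X <- matrix(rnorm(d * n), d, n)
  X[1, ] <- 5  # constant gene
  p <- screen_genes(sn, X)
  expect_length(p, d)
  expect_equal(p[1], 1)
  perm <- sample(d)
  expect_equal(screen_genes(sn, X[perm, ]), p[perm], tolerance = 1e-12)
  # duplicated gene gets identical p on both rows
  X2 <- rbind(X, X[5, ])
  p2 <- screen_genes(sn, X2)
  expect_equal(p2[d + 1], p2[5])
  # empty snapshot warns and returns ones
  co <- patient_cohort(c(10, 20), c(5, 5))
  expect_warning(p0 <- screen_genes(take_snapshot(co, 1), X[, 1:2]),
                 "empty snapshot")
  expect_equal(p0, rep(1, d))
  # details frame carries the fitted quantities
  det <- screen_genes(sn, X, details = TRUE)
  expect_named(det, c("gene_id", "beta_hat", "se", "p_raw", "status"))
  expect_equal(det$p_raw, p)
})

test_that("zero-length observed times are dropped from the risk set", {
  co <- patient_cohort(c(0, 2, 4, 25), c(10, 3, 30, 8))
  sn <- take_snapshot(co, 25)  # 4th patient arrives exactly at t
  expect_equal(sn$n, 4L)
  expect_equal(sn$time[4], 0)
  x <- c(1, -1, 2, 100)  # huge value on the zero-length record
  r <- fit_cox_gene(sn, x)
  # identical to the fit that excludes the zero-length record
  sn3 <- make_snapshot(sn$time[1:3], sn$event[1:3])
  r3 <- fit_cox_gene(sn3, x[1:3])
  expect_equal(r$beta_hat, r3$beta_hat, tolerance = 1e-10)
  expect_equal(r$p, r3$p, tolerance = 1e-10)
})

test_that("null p-values are approximately uniform with enough events", {
  set.seed(77)
  des <- study_design(N = 50, l1 = 60, l2 = 60, M1 = 2, M2 = 2)
  pooled <- c()
  for (r in 1:3) {
    co <- simulate_patients(des, survival_model(lambda = 60))
    ev <- build_effect_vector(400, effect_model(tau = 0))
    X <- simulate_expression(co, ev, correlation_model(rho = 0))
    sn <- take_snapshot(co, 120)
    expect_gte(sum(sn$event), 20)
    pooled <- c(pooled, screen_genes(sn, X))
  }
  ks <- suppressWarnings(ks.test(pooled, "punif"))$statistic
  expect_lt(ks, 1.63 / sqrt(length(pooled)))  # 1% critical value
})
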