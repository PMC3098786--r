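small_cfg <- function(...) {
  simulation_config(
    design = study_design(N = 50, l1 = 60, l2 = 60, M1 = 2, M2 = 2),
    d = 150, n_runs = 3, seed = 42, ...)
}

test_that("run_study is deterministic and internally consistent", {
  cfg <- small_cfg()
  a <- run_study(cfg, 7)
  b <- run_study(cfg, 7)
  expect_identical(a, b)
  expect_equal(nrow(a$looks), 4)
  expect_true(all(diff(a$looks$n) >= 0))
  expect_true(all(diff(a$looks$events) >= 0))
  expect_equal(a$looks$n[cfg$design$M1], cfg$design$N)
  # stop flag consistent with apr vs threshold
  expect_equal(a$looks$stop_fixed,
               a$looks$apr_fixed >= cfg$design$apr_threshold)
  fs <- a$first_stop[["fixed-theta"]]
  if (fs <= 4) expect_true(a$looks$stop_fixed[fs])
})

test_that("tau = 0 studies have zero true APR and almost never reject", {
  cfg <- small_cfg(effect = effect_model(tau = 0))
  run <- suppressWarnings(run_study(cfg, 3))
  expect_equal(run$truth_d1, 0L)
  expect_equal(run$looks$APR_true, rep(0, 4))
  expect_equal(run$looks$FDP, as.numeric(run$looks$R > 0))
})

test_that("true APR increases across recruitment looks with strong effects", {
  cfg <- simulation_config(
    design = study_design(N = 50, l1 = 60, l2 = 60, M1 = 2, M2 = 2),
    effect = effect_model(tau = 0.5, sd = 1.5, step = 1),
    d = 400, n_runs = 1, seed = 1)
  looks <- suppressWarnings(
    lapply(1:40, function(r) run_study(cfg, 100 + r)$looks))
  apr1 <- vapply(looks, function(l) l$APR_true[1], numeric(1))
  apr2 <- vapply(looks, function(l) l$APR_true[2], numeric(1))
  # accumulating information: more samples never lose power, and the only
  # non-increases are runs where both early looks detect nothing (the BH
  # cascade has not started yet)
  expect_gte(mean(apr2 >= apr1), 0.95)
  expect_gte(mean(apr2 > apr1), 0.8)
  started <- apr2 > 0
  expect_gte(mean(apr2[started] > apr1[started]), 0.95)
})

test_that("run_monte_carlo aggregates runs and stop fractions partition", {
  cfg <- small_cfg()
  mc <- run_monte_carlo(cfg)
  expect_equal(nrow(mc$per_look), 4)
  expect_equal(dim(mc$first_stop), c(3L, 2L))
  for (key in c("fixed", "smooth")) {
    fr <- mc$per_look[[paste0("stopfrac_", key)]]
    v <- c("fixed" = "fixed-theta", "smooth" = "smoother")[key]
    expect_equal(sum(fr) + mc$never_stopped[[v]], 1)
  }
  # n_runs = 1: summary equals that run's values and SDs are 0
  cfg1 <- small_cfg(); cfg1$n_runs <- 1L
  mc1 <- run_monte_carlo(cfg1)
  r1 <- run_study(cfg1, cfg1$seed + 1)
  expect_equal(mc1$per_look$R_mean, r1$looks$R)
  expect_equal(mc1$per_look$FDP_sd, rep(0, 4))
  expect_equal(mean_first_stop(mc1, "fixed-theta", never = "M+1"),
               as.numeric(r1$first_stop[["fixed-theta"]]))
})

test_that("profiles encode the named parameterizations", {
  p1 <- profile_config("table1")
  expect_equal(p1$design$M, 4)
  expect_equal(p1$d, 10000L)
  expect_equal(p1$n_runs, 1000L)
  expect_equal(p1$survival$lambda, 60)
  p2 <- profile_config("table2", d = 500, n_runs = 5)
  expect_equal(p2$design$M, 10)
  expect_equal(p2$d, 500L)
  p5 <- profile_config("tau5")
  expect_equal(p5$effect$tau, 0.05)
  bp <- profile_config("breastparam")
  expect_equal(bp$d, 24496L)
  expect_equal(bp$design$N, 295)
  expect_equal(bp$corr$sigma2, 0.1)
  expect_equal(bp$survival$family, "lognormal")
  expect_error(profile_config("breastparam", d = 100), "table mode")
})

test_that("config files round-trip and unknown keys are rejected", {
  cfg <- small_cfg()
  path <- withr::local_tempfile(fileext = ".txt")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$design, cfg$design)
  expect_equal(cfg2$effect, cfg$effect)
  expect_equal(cfg2$corr, cfg$corr)
  expect_equal(cfg2$d, cfg$d)
  expect_equal(cfg2$n_runs, cfg$n_runs)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("N: 10", "l1: 60", "l2: 60", "M1: 1", "M2: 1",
               "frobnicate: yes"), bad)
  expect_error(read_sim_config(bad), "unknown config key")
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("N: 10", "N: 20", "l1: 60", "l2: 60", "M1: 1", "M2: 1"), dup)
  expect_error(read_sim_config(dup), "duplicate")
})

test_that("run_on_data applies the pipeline to user tables", {
  set.seed(60)
  n <- 12; d <- 25
  patients <- data.frame(patient_id = paste0("P", 1:n),
                         arrival_month = runif(n, 0, 20),
                         survival_month = rexp(n, 1 / 15),
                         event = rbinom(n, 1, 0.8))
  expr <- matrix(rnorm(d * n), d, n,
                 dimnames = list(paste0("g", 1:d), patients$patient_id))
  des <- study_design(N = n, l1 = 20, l2 = 30, M1 = 2, M2 = 2)
  res <- suppressWarnings(run_on_data(expr, patients, des))
  expect_equal(nrow(res), 4)
  expect_true(all(diff(res$n) >= 0))
  expect_equal(res$n[4], n)
  expect_false(any(c("FDP", "APR_true") %in% names(res)))
  # column order of expr must not matter (alignment by id)
  perm <- sample(n)
  res2 <- suppressWarnings(run_on_data(expr[, perm], patients, des))
  expect_equal(res2, res)
  # misaligned ids are named in the error
  colnames(expr)[1] <- "WRONG"
  expect_error(run_on_data(expr, patients, des), "WRONG")
})

test_that("pure-noise user data yields no discoveries at any look", {
  n <- 30; d <- 200
  des <- study_design(N = n, l1 = 20, l2 = 30, M1 = 2, M2 = 2)
  # under the global null each look rejects with probability <= alpha, so
  # most data draws see zero discoveries at every look
  clean <- vapply(1:10, function(s) {
    set.seed(600 + s)
    patients <- data.frame(patient_id = paste0("P", 1:n),
                           survival_month = rexp(n, 1 / 15))
    expr <- matrix(rnorm(d * n), d, n,
                   dimnames = list(paste0("g", 1:d), patients$patient_id))
    res <- suppressWarnings(
      run_on_data(expr, patients, des, arrival_seed = s))
    all(res$R == 0)
  }, logical(1))
  expect_gte(mean(clean), 0.7)
})
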