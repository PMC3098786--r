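#' Full configuration of a simulated interim-analysis study
#'
#' Bundles the trial geometry with the generative models and the
#' Monte-Carlo settings.  The defaults are desk-scale (d = 1000 genes,
#' 50 runs); [profile_config()] provides the named full-scale
#' parameterizations.
#'
#' @param design a [study_design()].
#' @param survival a [survival_model()].
#' @param effect an [effect_model()].
#' @param corr a [correlation_model()].
#' @param d number of genes on the array.
#' @param variants APR-estimator variants to evaluate at each look:
#'   subset of `c("fixed-theta", "smoother")`.
#' @param theta pi0 tail threshold for the fixed-theta variant.
#' @param n_runs number of Monte-Carlo replicates.
#' @param seed base seed; run r uses seed `seed + r`.
#' @param signal_group group (1 short / 2 long survivors) carrying the
#'   expression shift.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(design,
                              survival = survival_model(),
                              effect = effect_model(),
                              corr = correlation_model(),
                              d = 1000,
                              variants = c("fixed-theta", "smoother"),
                              theta = 0.5,
                              n_runs = 50,
                              seed = 1,
                              signal_group = 2L) {
  stopifnot(inherits(design, "study_design"),
            inherits(survival, "survival_model"),
            inherits(effect, "effect_model"),
            inherits(corr, "correlation_model"),
            d >= 1, n_runs >= 1)
  variants <- match.arg(variants, c("fixed-theta", "smoother"),
                        several.ok = TRUE)
  structure(list(design = design, survival = survival, effect = effect,
                 corr = corr, d = as.integer(d), variants = variants,
                 theta = theta, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), signal_group = as.integer(signal_group)),
            class = "simulation_config")
}

#' Named full-scale simulation profiles
#'
#' `"table1"`: N = 50, recruitment and follow-up of 60 months each,
#' M1 = M2 = 2 looks, exponential survival with mean 60 months, tau = 50%
#' altered genes with large discretized-normal effects, d = 10000 genes,
#' 1000 runs.  `"table2"`: the same with M1 = M2 = 5.  `"tau5"`:
#' M1 = M2 = 5 with only tau = 5% altered genes.  `"breastparam"`: 295
#' patients, 11-year recruitment, log-normal survival (median 84 months),
#' effect shifts from the packaged breast-cancer value/count table
#' (24496 genes), marginal variance 0.1, APR stop threshold 50%.
#'
#' @param name profile name.
#' @param d,n_runs optional overrides for desk-scale runs.
#' @param seed base seed.
#' @return A [simulation_config()].
#' @export
profile_config <- function(name = c("table1", "table2", "tau5", "breastparam"),
                           d = NULL, n_runs = NULL, seed = 1) {
  name <- match.arg(name)
  if (name == "breastparam") {
    tab <- read_effect_table(system.file("extdata", "breast_effect_table.tsv",
                                         package = "survinterim"))
    cfg <- simulation_config(
      design = study_design(N = 295, l1 = 132, l2 = 84, M1 = 5, M2 = 5,
                            fdr_level = 0.05, apr_threshold = 0.5),
      survival = survival_model("lognormal", meanlog = log(84), sdlog = 0.8),
      effect = effect_model("table", table = tab),
      corr = correlation_model(rho = 0.5, sigma2 = 0.1),
      d = sum(tab$count), n_runs = 1000, seed = seed)
  } else {
    M1 <- if (name == "table1") 2L else 5L
    tau <- if (name == "tau5") 0.05 else 0.5
    cfg <- simulation_config(
      design = study_design(N = 50, l1 = 60, l2 = 60, M1 = M1, M2 = M1,
                            fdr_level = 0.05, apr_threshold = 0.8),
      survival = survival_model("exponential", lambda = 60),
      effect = effect_model("discretized-normal", tau = tau,
                            sd = 1.5, step = 1.0),
      corr = correlation_model(rho = 0.5, sigma2 = 1),
      d = 10000, n_runs = 1000, seed = seed)
  }
  if (!is.null(d)) {
    if (cfg$effect$mode == "table")
      stop("cannot override d in table mode (d is fixed by the effect table)")
    cfg$d <- as.integer(d)
  }
  if (!is.null(n_runs)) cfg$n_runs <- as.integer(n_runs)
  cfg
}

#' Run one simulated study through all its analyses
#'
#' Simulates one cohort and expression matrix, schedules the M looks, and
#' at each look takes the accumulated-data snapshot, screens all genes by
#' Cox regression, applies BH at the full nominal FDR level, computes the
#' truth-aware confusion metrics and the APR estimates, and records the
#' stop flag of each estimator variant.  All M looks are computed even
#' after a stop flag fires: stopping is recorded, not enforced, so that
#' per-look summaries cover every run and stop fractions can still be
#' derived.
#'
#' @param config a [simulation_config()].
#' @param run_seed integer seed for this run; the run is deterministic
#'   given `(config, run_seed)`.
#' @return An object of class `study_run`: `seed`, `looks` (one row per
#'   analysis), `first_stop` (named by variant; `M + 1` if the threshold is
#'   never reached), `truth_d1`.
#' @export
run_study <- function(config, run_seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(run_seed))
  des <- config$design
  cohort <- simulate_patients(des, config$survival)
  effects <- build_effect_vector(config$d, config$effect)
  X <- simulate_expression(cohort, effects, config$corr,
                           signal_group = config$signal_group)
  sched <- schedule_analyses(des, cohort$arrivals)

  nv <- length(config$variants)
  rows <- vector("list", des$M)
  first_stop <- stats::setNames(rep(des$M + 1L, nv), config$variants)
  for (m in seq_len(des$M)) {
    sn <- take_snapshot(cohort, sched$times[m])
    p <- screen_genes(sn, X)
    reject <- which(bh_adjust(p) <= des$fdr_level)
    cm <- confusion_metrics(reject, effects)
    row <- list(analysis = m, t = sched$times[m], phase = sched$phase[m],
                n = sn$n, events = sum(sn$event),
                R = cm$R, FP = cm$FP, TP = cm$TP,
                FDP = cm$FDP, APR_true = cm$APR_true)
    for (v in config$variants) {
      est <- estimate_apr(p, des$fdr_level, pi0_method = v,
                          theta = config$theta)
      stopv <- check_stop(est, des$apr_threshold)
      key <- variant_key(v)
      row[[paste0("apr_", key)]] <- est$apr_hat
      row[[paste0("pi0_", key)]] <- est$pi0_hat
      row[[paste0("stop_", key)]] <- stopv
      if (stopv && first_stop[v] > des$M) first_stop[v] <- m
    }
    row$alpha_BH <- bh_alpha(p, des$fdr_level)
    rows[[m]] <- row
  }
  looks <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(seed = run_seed, looks = looks, first_stop = first_stop,
                 truth_d1 = effects$d1),
            class = "study_run")
}

variant_key <- function(v) c("fixed-theta" = "fixed", "smoother" = "smooth")[v]

#' @export
print.study_run <- function(x, ...) {
  cat("Simulated study run (seed ", x$seed, "), ", nrow(x$looks),
      " analyses, d1 = ", x$truth_d1, " true genes\n", sep = "")
  print(x$looks[, c("analysis", "t", "n", "events", "R", "FDP",
                    "APR_true")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Monte-Carlo replication of a simulated study
#'
#' Executes `config$n_runs` independent [run_study()] replicates (run r
#' uses seed `config$seed + r`, so the set of runs is reproducible and
#' order-independent) and aggregates per-analysis means and standard
#' deviations of the rejection count, the false discovery proportion, the
#' true APR and each APR-estimator variant, together with the fraction of
#' runs whose first stop falls at each look.  Every look of every run is
#' computed; nothing is conditioned on not having stopped earlier.
#'
#' @param config a [simulation_config()].
#' @param progress print per-run progress to standard error.
#' @return An object of class `mc_summary`: `per_look` (one row per
#'   analysis with `*_mean` / `*_sd` columns and `stopfrac_*`),
#'   `first_stop` (runs x variants matrix, `M + 1` = never stopped),
#'   `never_stopped` fractions, `n_runs`, and the `config` echo.
#' @export
run_monte_carlo <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  M <- config$design$M
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    runs[[r]] <- run_study(config, config$seed + r)
    if (progress && r %% 10 == 0)
      message("run ", r, "/", config$n_runs)
  }
  keys <- variant_key(config$variants)
  metric_cols <- c("R", "FDP", "APR_true", paste0("apr_", keys))
  per_look <- data.frame(analysis = seq_len(M),
                         phase = runs[[1]]$looks$phase,
                         t_mean = rowMeans(sapply(runs, function(x) x$looks$t)),
                         n_mean = rowMeans(sapply(runs, function(x) x$looks$n)),
                         events_mean = rowMeans(sapply(runs, function(x) x$looks$events)))
  for (cn in metric_cols) {
    vals <- sapply(runs, function(x) x$looks[[cn]])  # M x n_runs
    vals <- matrix(vals, nrow = M)
    per_look[[paste0(cn, "_mean")]] <- rowMeans(vals)
    sds <- apply(vals, 1, stats::sd)
    sds[is.na(sds)] <- 0  # single-run summaries have zero spread
    per_look[[paste0(cn, "_sd")]] <- sds
  }
  first_stop <- t(sapply(runs, function(x) x$first_stop))
  first_stop <- matrix(first_stop, ncol = length(config$variants),
                       dimnames = list(NULL, config$variants))
  for (i in seq_along(config$variants)) {
    fs <- first_stop[, i]
    per_look[[paste0("stopfrac_", keys[i])]] <-
      vapply(seq_len(M), function(m) mean(fs == m), numeric(1))
  }
  structure(list(per_look = per_look, first_stop = first_stop,
                 never_stopped = colMeans(first_stop > M),
                 n_runs = config$n_runs, config = config),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Monte-Carlo summary over ", x$n_runs, " runs (d = ",
      x$config$d, " genes)\n", sep = "")
  show <- c("analysis", "n_mean", "events_mean", "R_mean", "FDP_mean",
            "APR_true_mean",
            grep("^apr_.*_mean$", names(x$per_look), value = TRUE),
            grep("^stopfrac_", names(x$per_look), value = TRUE))
  print(x$per_look[, show], row.names = FALSE, digits = 3)
  for (v in colnames(x$first_stop))
    cat(sprintf("never stopped (%s): %.1f%%\n", v,
                100 * x$never_stopped[v]))
  invisible(x)
}

#' Mean first-stop analysis index
#'
#' Averages, across runs, the index of the first analysis at which the
#' chosen APR-estimator variant reached the stop threshold.  Runs that
#' never reach the threshold end at the final analysis anyway, so they
#' contribute the final index M (set `never = "M+1"` to use the sentinel
#' instead).
#'
#' @param mc an [run_monte_carlo()] summary.
#' @param variant estimator variant name.
#' @param never how never-stopped runs enter the mean.
#' @return the (unrounded) mean index.
#' @export
mean_first_stop <- function(mc, variant = "fixed-theta",
                            never = c("M", "M+1")) {
  stopifnot(inherits(mc, "mc_summary"))
  never <- match.arg(never)
  fs <- mc$first_stop[, variant]
  M <- mc$config$design$M
  if (never == "M") fs <- pmin(fs, M)
  mean(fs)
}

#' Per-look summary table output
#'
#' Writes the per-analysis Monte-Carlo summary as delimited text.
#'
#' @param mc an [run_monte_carlo()] summary.
#' @param path output path (extension selects the delimiter).
#' @export
write_mc_summary <- function(mc, path) {
  stopifnot(inherits(mc, "mc_summary"))
  utils::write.table(mc$per_look, path, sep = guess_sep(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the interim-analysis pipeline to user-supplied data
#'
#' Runs the same per-look pipeline as [run_study()] -- snapshot, gene-wise
#' Cox screen, BH adjustment, APR estimation, stop flag -- on a real
#' expression matrix and patient table.  No truth metrics are available.
#' Patient survival is taken as observed follow-up (column
#' `survival_month`) with an `event` indicator (1 = died; assumed 1 when
#' the column is absent).  When the patient table has no `arrival_month`
#' column, arrival times are drawn Uniform(0, l1_intended) under
#' `arrival_seed`.
#'
#' @param expr numeric `d x n` matrix, genes in rows, colnames = patient
#'   ids.
#' @param patients data.frame with columns `patient_id`, `survival_month`,
#'   optionally `event` and `arrival_month`.
#' @param design a [study_design()] with `N = nrow(patients)`.
#' @param variants,theta APR-estimator settings as in
#'   [simulation_config()].
#' @param arrival_seed seed used when arrival times must be drawn.
#' @return data.frame with one row per analysis: `analysis`, `t`, `n`,
#'   `events`, `R`, `alpha_BH` and per-variant `apr_*` / `stop_*` columns.
#' @export
run_on_data <- function(expr, patients, design,
                        variants = c("fixed-theta", "smoother"),
                        theta = 0.5, arrival_seed = 1) {
  stopifnot(is.matrix(expr), inherits(design, "study_design"))
  variants <- match.arg(variants, c("fixed-theta", "smoother"),
                        several.ok = TRUE)
  if (!all(c("patient_id", "survival_month") %in% names(patients)))
    stop("patient table needs columns patient_id and survival_month")
  if (design$N != nrow(patients))
    stop("design N (", design$N, ") does not match patient count (",
         nrow(patients), ")")
  if (!is.null(colnames(expr))) {
    bad <- setdiff(colnames(expr), patients$patient_id)
    bad2 <- setdiff(patients$patient_id, colnames(expr))
    if (length(bad) || length(bad2))
      stop("sample ids do not align; offending: ",
           paste(unique(c(bad, bad2)), collapse = ", "))
    expr <- expr[, match(patients$patient_id, colnames(expr)), drop = FALSE]
  } else if (ncol(expr) != nrow(patients)) {
    stop("expression matrix has ", ncol(expr), " columns for ",
         nrow(patients), " patients and no sample ids to align by")
  }
  if (is.null(patients$arrival_month)) {
    set.seed(as.integer(arrival_seed))
    patients$arrival_month <- stats::runif(nrow(patients), 0,
                                           design$l1_intended)
  }
  ev_base <- if (is.null(patients$event)) rep(1L, nrow(patients))
             else as.integer(patients$event)
  sched <- schedule_analyses(design, patients$arrival_month)
  a <- patients$arrival_month
  s <- patients$survival_month
  rows <- vector("list", design$M)
  for (m in seq_len(design$M)) {
    t <- sched$times[m]
    inc <- which(a <= t)
    fu <- t - a[inc]
    died <- s[inc] <= fu & ev_base[inc] == 1L
    sn <- structure(list(index = inc,
                         time = pmin(s[inc], fu),
                         event = as.integer(died),
                         t = t, n = length(inc)),
                    class = "survival_snapshot")
    p <- screen_genes(sn, expr)
    row <- list(analysis = m, t = t, phase = sched$phase[m],
                n = sn$n, events = sum(sn$event),
                R = sum(bh_adjust(p) <= design$fdr_level),
                alpha_BH = bh_alpha(p, design$fdr_level))
    for (v in variants) {
      est <- estimate_apr(p, design$fdr_level, pi0_method = v, theta = theta)
      key <- variant_key(v)
      row[[paste0("apr_", key)]] <- est$apr_hat
      row[[paste0("pi0_", key)]] <- est$pi0_hat
      row[[paste0("stop_", key)]] <- check_stop(est, design$apr_threshold)
    }
    rows[[m]] <- row
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
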