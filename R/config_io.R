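#' Read a simulation configuration from a flat key/value file
#'
#' The file format is one `key: value` pair per line (YAML-like scalars
#' only; `#` starts a comment).  Recognized keys mirror the
#' [simulation_config()] components:
#'
#' * design: `N`, `l1`, `l2`, `M1`, `M2`, `fdr_level`, `apr_threshold`
#' * survival: `survival_family` (`exponential`/`lognormal`), `lambda`,
#'   `meanlog`, `sdlog`
#' * effect: `effect_mode` (`discretized-normal`/`table`), `tau`,
#'   `effect_sd`, `effect_step`, `effect_table` (path to a value/count
#'   table)
#' * correlation: `rho`, `sigma2`
#' * engine: `d`, `theta`, `n_runs`, `seed`, `variants`
#'   (comma-separated), `signal_group`
#'
#' Unknown keys are rejected with an error.
#'
#' @param path configuration file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad))
    stop("cannot parse config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  known <- c("N", "l1", "l2", "M1", "M2", "fdr_level", "apr_threshold",
             "survival_family", "lambda", "meanlog", "sdlog",
             "effect_mode", "tau", "effect_sd", "effect_step", "effect_table",
             "rho", "sigma2",
             "d", "theta", "n_runs", "seed", "variants", "signal_group")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
  }
  chr <- function(key, default) {
    if (is.null(cfg[[key]])) default else cfg[[key]]
  }
  need <- c("N", "l1", "l2", "M1", "M2")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
  design <- study_design(N = num("N", NA), l1 = num("l1", NA),
                         l2 = num("l2", NA), M1 = num("M1", NA),
                         M2 = num("M2", NA),
                         fdr_level = num("fdr_level", 0.05),
                         apr_threshold = num("apr_threshold", 0.8))
  family <- chr("survival_family", "exponential")
  survival <- if (family == "exponential")
    survival_model("exponential", lambda = num("lambda", 60))
  else
    survival_model("lognormal", meanlog = num("meanlog", log(84)),
                   sdlog = num("sdlog", 0.8))
  mode <- chr("effect_mode", "discretized-normal")
  effect <- if (mode == "table") {
    tabpath <- chr("effect_table", NULL)
    if (is.null(tabpath)) stop("effect_mode: table requires effect_table")
    effect_model("table", table = read_effect_table(tabpath))
  } else {
    effect_model("discretized-normal", tau = num("tau", 0.5),
                 sd = num("effect_sd", 1.0), step = num("effect_step", 0.2))
  }
  d <- if (mode == "table") sum(effect$table$count) else num("d", 1000)
  variants <- strsplit(chr("variants", "fixed-theta,smoother"), ",")[[1]]
  simulation_config(design = design, survival = survival, effect = effect,
                    corr = correlation_model(rho = num("rho", 0.5),
                                             sigma2 = num("sigma2", 1)),
                    d = d, variants = trimws(variants),
                    theta = num("theta", 0.5),
                    n_runs = num("n_runs", 50), seed = num("seed", 1),
                    signal_group = num("signal_group", 2))
}

#' Write a configuration echo
#'
#' Writes the scalar components of a [simulation_config()] back to a flat
#' key/value file readable by [read_sim_config()] (table-mode effect
#' tables are referenced by the path given in `effect_table`).
#'
#' @param config a [simulation_config()].
#' @param path output path.
#' @param effect_table path to the effect table, for table mode.
#' @export
write_sim_config <- function(config, path, effect_table = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  des <- config$design
  lines <- c(
    sprintf("N: %d", des$N), sprintf("l1: %g", des$l1_intended),
    sprintf("l2: %g", des$l2), sprintf("M1: %d", des$M1),
    sprintf("M2: %d", des$M2),
    sprintf("fdr_level: %g", des$fdr_level),
    sprintf("apr_threshold: %g", des$apr_threshold),
    sprintf("survival_family: %s", config$survival$family))
  lines <- c(lines, if (config$survival$family == "exponential")
    sprintf("lambda: %g", config$survival$lambda)
    else c(sprintf("meanlog: %g", config$survival$meanlog),
           sprintf("sdlog: %g", config$survival$sdlog)))
  lines <- c(lines, sprintf("effect_mode: %s", config$effect$mode))
  lines <- c(lines, if (config$effect$mode == "table") {
    if (is.null(effect_table)) character(0)
    else sprintf("effect_table: %s", effect_table)
  } else c(sprintf("tau: %g", config$effect$tau),
           sprintf("effect_sd: %g", config$effect$sd),
           sprintf("effect_step: %g", config$effect$step)))
  lines <- c(lines,
             sprintf("rho: %g", config$corr$rho),
             sprintf("sigma2: %g", config$corr$sigma2),
             sprintf("d: %d", config$d),
             sprintf("theta: %g", config$theta),
             sprintf("n_runs: %d", config$n_runs),
             sprintf("seed: %d", config$seed),
             sprintf("variants: %s", paste(config$variants, collapse = ",")),
             sprintf("signal_group: %d", config$signal_group))
  writeLines(lines, path)
  invisible(path)
}
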