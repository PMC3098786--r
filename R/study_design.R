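#' Define a two-phase survival study design
#'
#' A study consists of a recruitment phase of intended length `l1` months,
#' during which `N` patients arrive, followed by a follow-up phase of length
#' `l2` months during which no new patients enter but survival information
#' keeps accruing.  `M1` interim analyses are scheduled during recruitment
#' (one every `N/M1` new patients) and `M2` during follow-up (equally spaced
#' in time).  The final analysis is the `M1+M2`-th look.
#'
#' @param N planned total number of patients (>= 2).
#' @param l1 intended length of the recruitment phase, months.
#' @param l2 length of the follow-up phase, months (may be 0).
#' @param M1 number of analyses during recruitment (>= 1, <= N).
#' @param M2 number of analyses during follow-up (>= 1).
#' @param fdr_level nominal FDR level alpha used at every look; no
#'   interim-specific alpha-spending is applied.
#' @param apr_threshold estimated-APR level at which the study may stop
#'   early (inclusive comparison).
#'
#' @return An object of class `study_design`.
#' @examples
#' study_design(N = 50, l1 = 60, l2 = 60, M1 = 2, M2 = 2)
#' @export
study_design <- function(N, l1, l2, M1, M2,
                         fdr_level = 0.05, apr_threshold = 0.8) {
  stopifnot(length(N) == 1L, length(l1) == 1L, length(l2) == 1L,
            length(M1) == 1L, length(M2) == 1L)
  N <- as.integer(N); M1 <- as.integer(M1); M2 <- as.integer(M2)
  if (N < 2L) stop("invalid design: N must be >= 2")
  if (M1 < 1L || M2 < 1L) stop("invalid design: M1 and M2 must be >= 1")
  if (N < M1) stop("invalid design: more recruitment analyses (M1) than patients (N)")
  if (!(l1 > 0)) stop("invalid design: l1 must be > 0")
  if (l2 < 0) stop("invalid design: l2 must be >= 0")
  if (!(fdr_level > 0 && fdr_level < 1)) stop("invalid design: fdr_level must be in (0,1)")
  if (!(apr_threshold > 0 && apr_threshold <= 1)) stop("invalid design: apr_threshold must be in (0,1]")
  structure(
    list(N = N, l1_intended = as.numeric(l1), l2 = as.numeric(l2),
         M1 = M1, M2 = M2, M = M1 + M2,
         fdr_level = fdr_level, apr_threshold = apr_threshold),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Two-phase survival study design\n")
  cat(sprintf("  N = %d patients; recruitment <= %g months, follow-up %g months\n",
              x$N, x$l1_intended, x$l2))
  cat(sprintf("  analyses: %d during recruitment + %d during follow-up (M = %d)\n",
              x$M1, x$M2, x$M))
  cat(sprintf("  FDR level %.3g, APR stop threshold %.3g\n",
              x$fdr_level, x$apr_threshold))
  invisible(x)
}

#' Construct a patient cohort
#'
#' Bundles per-patient arrival times (months since study start) and true
#' survival times (months from arrival to death) together with the latent
#' short/long-survivor group label that carries the expression signal in
#' simulations.
#'
#' @param arrivals numeric vector of arrival times, months since study start.
#' @param survival numeric vector of true survival times (> 0), months from
#'   arrival to death.
#' @param group integer/factor-like vector: 1 = short survivor, 2 = long
#'   survivor.  Optional for user data (`NULL`).
#' @return An object of class `patient_cohort`.
#' @export
patient_cohort <- function(arrivals, survival, group = NULL) {
  stopifnot(length(arrivals) == length(survival))
  if (any(survival <= 0)) stop("survival times must be > 0")
  if (any(arrivals < 0)) stop("arrival times must be >= 0")
  if (!is.null(group)) {
    stopifnot(length(group) == length(arrivals), all(group %in% c(1L, 2L)))
    group <- as.integer(group)
  }
  structure(list(arrivals = as.numeric(arrivals),
                 survival = as.numeric(survival),
                 group = group,
                 N = length(arrivals)),
            class = "patient_cohort")
}

#' Schedule the interim and final analyses of a study
#'
#' Recruitment-phase analysis m (m = 1..M1) takes place at the arrival time
#' of the k-th patient, k = round(m * N / M1) (round-half-up), with patients
#' ordered by arrival; the M1-th look therefore falls at the actual end of
#' recruitment, l1 = max(arrivals).  Follow-up analysis m (m = 1..M2) takes
#' place at l1 + (m / M2) * l2, i.e. at equally spaced calendar times, the
#' last one being the final analysis at l1 + l2.
#'
#' @param design a [study_design()].
#' @param arrivals numeric vector of length `design$N` of arrival times in
#'   `[0, design$l1_intended]`.
#' @return An object of class `analysis_schedule` with components `times`
#'   (length M), `phase` (`"recruitment"` / `"follow-up"`), and `n`
#'   (patients arrived by each analysis time).
#' @examples
#' d <- study_design(N = 4, l1 = 60, l2 = 60, M1 = 2, M2 = 2)
#' schedule_analyses(d, c(2, 5, 9, 12))  # looks at months 5, 12, 42, 72
#' @export
schedule_analyses <- function(design, arrivals) {
  stopifnot(inherits(design, "study_design"))
  if (length(arrivals) != design$N)
    stop("arrivals must have length N = ", design$N)
  if (any(arrivals < 0) || any(arrivals > design$l1_intended))
    stop("arrivals must lie in [0, l1_intended]")
  a_sorted <- sort(arrivals)
  l1_actual <- max(arrivals)
  m1 <- seq_len(design$M1)
  # round-half-up patient index for each recruitment look
  k <- floor(m1 * design$N / design$M1 + 0.5)
  k[design$M1] <- design$N  # guard: last recruitment look sees everyone
  t_recr <- a_sorted[k]
  m2 <- seq_len(design$M2)
  t_fup <- l1_actual + (m2 / design$M2) * design$l2
  times <- c(t_recr, t_fup)
  phase <- rep(c("recruitment", "follow-up"), c(design$M1, design$M2))
  n <- vapply(times, function(t) sum(arrivals <= t), integer(1))
  structure(list(times = times, phase = phase, n = n,
                 l1_actual = l1_actual, M = design$M),
            class = "analysis_schedule")
}

#' @export
print.analysis_schedule <- function(x, ...) {
  cat("Analysis schedule (", x$M, " looks)\n", sep = "")
  print(data.frame(analysis = seq_len(x$M), time = x$times,
                   phase = x$phase, n = x$n), row.names = FALSE)
  invisible(x)
}

#' Administratively censored view of a cohort at one analysis time
#'
#' At calendar time `t` the analysis sees exactly the patients who have
#' arrived (`a_j <= t`).  Each included patient contributes the pair
#' (observed time, event): the observed time is `min(s_j, t - a_j)` and the
#' event indicator is 1 if the patient has already died (`s_j <= t - a_j`),
#' 0 if administratively censored at the analysis date.  A patient arriving
#' exactly at `t` is included with observed time 0; such zero-length records
#' carry no risk-set information and are dropped again by the Cox screen.
#'
#' @param cohort a [patient_cohort()].
#' @param t analysis time in months (>= 0).
#' @return An object of class `survival_snapshot` with components `index`
#'   (positions of included patients in the cohort), `time`, `event`, and
#'   `t`.
#' @export
take_snapshot <- function(cohort, t) {
  stopifnot(inherits(cohort, "patient_cohort"), t >= 0)
  inc <- which(cohort$arrivals <= t)
  fu <- t - cohort$arrivals[inc]
  s <- cohort$survival[inc]
  event <- as.integer(s <= fu)
  time <- pmin(s, fu)
  structure(list(index = inc, time = time, event = event, t = t,
                 n = length(inc)),
            class = "survival_snapshot")
}

#' @export
print.survival_snapshot <- function(x, ...) {
  cat(sprintf("Survival snapshot at t = %g months: %d patients, %d events\n",
              x$t, x$n, sum(x$event)))
  invisible(x)
}

#' Read or write a patient table
#'
#' Patient tables are delimited text with a header row and columns
#' `patient_id`, `arrival_month`, `survival_month` and optionally `event`.
#' The separator is auto-detected from the file extension (`.csv` = comma,
#' `.tsv`/`.txt` = tab) and falls back to whitespace.
#'
#' @param path file path.
#' @return `read_patient_table` returns a `data.frame`;
#'   `write_patient_table` invisibly returns `path`.
#' @export
read_patient_table <- function(path) {
  sep <- guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "arrival_month", "survival_month")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("patient table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_patient_table
#' @param cohort a [patient_cohort()] to write.
#' @export
write_patient_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "patient_cohort"))
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(cohort$N)),
                   arrival_month = cohort$arrivals,
                   survival_month = cohort$survival)
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

guess_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", "\t")
}
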