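#' Survival-time model for simulated cohorts
#'
#' Two families are supported.  `"exponential"` draws survival times from
#' Exp(1/lambda) with mean `lambda` months; patients are labelled short
#' survivors when their survival time is below `lambda`.  `"lognormal"`
#' draws from a log-normal with location `meanlog` and scale `sdlog` (on the
#' log-month scale); the short/long split is then made at the distribution
#' median exp(meanlog), mirroring a median-survival split of real data.
#'
#' @param family `"exponential"` or `"lognormal"`.
#' @param lambda mean survival time in months (exponential family).
#' @param meanlog,sdlog log-normal location and scale.
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(family = c("exponential", "lognormal"),
                           lambda = 60, meanlog = log(84), sdlog = 1) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (!(lambda > 0)) stop("lambda must be > 0")
  } else {
    if (!(sdlog > 0)) stop("sdlog must be > 0")
  }
  structure(list(family = family, lambda = lambda,
                 meanlog = meanlog, sdlog = sdlog),
            class = "survival_model")
}

#' Per-gene effect model for the long-survivor group
#'
#' The short-survivor group has mean expression 0 for every gene; the
#' long-survivor group has mean `mu2_i` for gene i.  In
#' `mode = "discretized-normal"` a random fraction `tau` of genes receives a
#' nonzero shift drawn from Normal(0, sd) and rounded to the nearest
#' multiple of `step` (zero-rounded draws are redrawn, so the declared
#' altered count is exact).  In `mode = "table"` the multiset of shifts is
#' given explicitly as (value, count) pairs and assigned to random gene
#' indices.
#'
#' @param mode `"discretized-normal"` or `"table"`.
#' @param tau fraction of genes altered in the long-survivor group.
#' @param sd standard deviation of the normal before discretization.
#'   The package's large-fold-change regime (the default, calibrated so
#'   the final-look true APR of the tau = 50%, M = 4 reference design is
#'   about 0.8) is `sd = 1.5, step = 1.0`; a small-fold-change regime is
#'   `sd = 0.8, step = 0.5`.
#' @param step discretization grid width.
#' @param table data.frame with columns `value` and `count` (table mode).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(mode = c("discretized-normal", "table"),
                         tau = 0.5, sd = 1.5, step = 1.0, table = NULL) {
  mode <- match.arg(mode)
  if (mode == "discretized-normal") {
    if (!(tau >= 0 && tau <= 1)) stop("tau must be in [0,1]")
    if (!(sd > 0)) stop("sd must be > 0")
    if (!(step > 0)) stop("step must be > 0")
  } else {
    if (is.null(table)) stop("table mode requires a (value, count) table")
    if (!all(c("value", "count") %in% names(table)))
      stop("effect table needs columns 'value' and 'count'")
    if (any(table$count < 0)) stop("effect table counts must be >= 0")
  }
  structure(list(mode = mode, tau = tau, sd = sd, step = step, table = table),
            class = "effect_model")
}

#' AR(1) correlation model for gene expression
#'
#' Genes are correlated along the array with an autoregressive structure:
#' cov(x_i, x_k) = sigma2 * rho^|i-k|, so neighbouring genes are strongly
#' correlated while distant genes are nearly independent.
#'
#' @param rho autoregressive base in `[0, 1)`.
#' @param sigma2 marginal variance of each gene.
#' @return An object of class `correlation_model`.
#' @export
correlation_model <- function(rho = 0.5, sigma2 = 1) {
  if (!(rho >= 0 && rho < 1)) stop("rho must be in [0,1)")
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  structure(list(rho = rho, sigma2 = sigma2), class = "correlation_model")
}

#' Simulate patient arrival and survival data
#'
#' Arrival times are iid Uniform(0, l1_intended); survival times are iid
#' draws from the survival model.  The latent group label (1 = short,
#' 2 = long survivor) is assigned by comparing each survival time with the
#' model's split point: lambda for the exponential family, the distribution
#' median for the log-normal family.
#'
#' @param design a [study_design()].
#' @param model a [survival_model()].
#' @return A [patient_cohort()].
#' @export
simulate_patients <- function(design, model = survival_model()) {
  stopifnot(inherits(design, "study_design"), inherits(model, "survival_model"))
  a <- stats::runif(design$N, 0, design$l1_intended)
  if (model$family == "exponential") {
    s <- stats::rexp(design$N, rate = 1 / model$lambda)
    split <- model$lambda
  } else {
    s <- stats::rlnorm(design$N, meanlog = model$meanlog, sdlog = model$sdlog)
    split <- exp(model$meanlog)
  }
  patient_cohort(a, s, group = ifelse(s < split, 1L, 2L))
}

#' Build the per-gene effect vector
#'
#' @param d number of genes.
#' @param model an [effect_model()].
#' @return An object of class `effect_vector` with components `mu2`
#'   (length d), `d`, `d1`, `alt_set` and `null_set`.
#' @examples
#' ev <- build_effect_vector(100, effect_model(tau = 0.5, sd = 1, step = 0.2))
#' ev$d1  # 50
#' @export
build_effect_vector <- function(d, model = effect_model()) {
  stopifnot(inherits(model, "effect_model"), d >= 1)
  d <- as.integer(d)
  mu2 <- numeric(d)
  if (model$mode == "discretized-normal") {
    d1 <- round(model$tau * d)
    if (d1 > 0) {
      alt <- sample.int(d, d1)
      draw_nonzero <- function(n) {
        v <- round(stats::rnorm(n, 0, model$sd) / model$step) * model$step
        while (any(v == 0))
          v[v == 0] <- round(stats::rnorm(sum(v == 0), 0, model$sd) /
                               model$step) * model$step
        v
      }
      mu2[alt] <- draw_nonzero(d1)
    }
  } else {
    tab <- model$table
    if (sum(tab$count) != d)
      stop("invalid effect table: counts sum to ", sum(tab$count),
           ", expected d = ", d)
    values <- rep(tab$value, tab$count)
    mu2 <- values[sample.int(d)]
  }
  alt_set <- which(mu2 != 0)
  structure(list(mu2 = mu2, d = d, d1 = length(alt_set),
                 alt_set = alt_set, null_set = which(mu2 == 0)),
            class = "effect_vector")
}

#' Simulate a correlated expression matrix for a cohort
#'
#' Each sample's column is a draw from a d-variate normal with AR(1)
#' covariance sigma2 * rho^|i-k|; long survivors (group 2) get mean vector
#' `mu2`, short survivors mean 0 (configurable via `signal_group`).  The
#' AR(1) draw is built sequentially, x_i = rho * x_{i-1} + sqrt(1-rho^2) * e_i,
#' which is O(d * n) and exactly equivalent to a dense Cholesky draw.
#'
#' @param cohort a [patient_cohort()] with group labels.
#' @param effects an [effect_vector()].
#' @param corr a [correlation_model()].
#' @param signal_group which group label (1 or 2) receives the mean shift
#'   `mu2`; the Cox test is sign-symmetric so this is a convention.
#' @return A numeric `d x n` matrix (genes in rows) with rownames
#'   `g<No>` and colnames matching cohort positions.
#' @export
simulate_expression <- function(cohort, effects, corr = correlation_model(),
                                signal_group = 2L) {
  stopifnot(inherits(cohort, "patient_cohort"),
            inherits(effects, "effect_vector"),
            inherits(corr, "correlation_model"))
  if (is.null(cohort$group))
    stop("cohort has no group labels; cannot place the expression signal")
  d <- effects$d; n <- cohort$N
  x <- ar1_normal(d, n, corr$rho) * sqrt(corr$sigma2)
  shift <- cohort$group == signal_group
  if (any(shift)) x[, shift] <- x[, shift] + effects$mu2
  dimnames(x) <- list(paste0("g", seq_len(d)), sprintf("S%04d", seq_len(n)))
  x
}

# d x n matrix of AR(1) standard-normal columns: unit marginals,
# corr(x_i, x_k) = rho^|i-k| down each column.
ar1_normal <- function(d, n, rho) {
  x <- matrix(stats::rnorm(d * n), nrow = d, ncol = n)
  if (rho > 0 && d > 1) {
    w <- sqrt(1 - rho^2)
    for (i in 2:d) x[i, ] <- rho * x[i - 1, ] + w * x[i, ]
  }
  x
}

#' Read an effect table (value/count pairs)
#'
#' Delimited text with header columns `value` and `count`.  The packaged
#' breast-cancer-parameterized table is available via
#' `system.file("extdata", "breast_effect_table.tsv", package = "survinterim")`;
#' it describes 24496 genes of which 8542 carry a nonzero mean shift.
#'
#' @param path file path.
#' @return data.frame with columns `value` and `count`.
#' @export
read_effect_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path))
  if (!all(c("value", "count") %in% names(df)))
    stop("effect table needs columns 'value' and 'count'")
  df
}

#' Read or write an expression matrix as delimited text
#'
#' Genes in rows; first column holds the gene id, remaining header fields
#' are sample ids.
#'
#' @param path file path.
#' @return `read_expression_matrix` returns a numeric matrix with gene
#'   rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param x numeric matrix, genes in rows.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
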