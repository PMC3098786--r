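#' Gene-wise Cox proportional-hazards screening
#'
#' Each gene i is tested for association with survival under the model
#' h(t | x_i) = h0(t) * exp(beta_i * x_ij): the baseline hazard h0 is never
#' estimated (it is profiled out by the partial likelihood) and the null
#' hypothesis H0i: beta_i = 0 is assessed by a two-sided Wald test.  The
#' partial likelihood uses Breslow tie handling and is maximized by a
#' safeguarded Newton iteration (step capping and step-halving on the
#' log-likelihood, at most `max_iter` iterations, |beta| capped at
#' `beta_cap`).  Genes for which the iteration does not converge or runs
#' into the cap -- typically monotone-separated genes at early looks with
#' very few events -- fall back to the score test at beta = 0.  Genes with
#' fewer than 2 events in the snapshot or constant expression are degenerate
#' and get p = 1.
#'
#' `fit_cox_gene` tests one gene; `screen_genes` tests all rows of an
#' expression matrix on the same snapshot (sharing the risk-set structure
#' across genes, which is what makes large screens fast).
#'
#' @param snapshot a [take_snapshot()] result.
#' @param expr numeric vector of expression values for one gene, aligned to
#'   the snapshot's included patients (or to the full cohort; see
#'   `matrix` below).
#' @return `fit_cox_gene` returns a list of class `cox_test_result` with
#'   `beta_hat`, `se`, `p`, `status` (`"ok"`, `"degenerate"`,
#'   `"fallback"`).
#' @examples
#' co <- patient_cohort(rep(0, 8), 1:8, group = rep(c(1L, 2L), each = 4))
#' sn <- take_snapshot(co, 100)
#' fit_cox_gene(sn, c(0, 0, 0, 0, 1, 1, 1, 1))
#' @export
fit_cox_gene <- function(snapshot, expr) {
  stopifnot(inherits(snapshot, "survival_snapshot"))
  x <- align_expr(snapshot, matrix(expr, nrow = 1))
  fit <- cox_fit_matrix(snapshot$time, snapshot$event, x)
  structure(list(beta_hat = fit$beta[1], se = fit$se[1], p = fit$p[1],
                 status = fit$status[1]),
            class = "cox_test_result")
}

#' @export
print.cox_test_result <- function(x, ...) {
  cat(sprintf("Cox gene test: beta = %.4g, se = %.4g, p = %.4g [%s]\n",
              x$beta_hat, x$se, x$p, x$status))
  invisible(x)
}

#' @rdname fit_cox_gene
#' @param matrix numeric `d x n` expression matrix, genes in rows.  Columns
#'   may span the full cohort (they are then subset to the snapshot's
#'   included patients by index) or exactly the included patients.
#' @param details if `TRUE` return a data.frame with columns `gene_id`,
#'   `beta_hat`, `se`, `p_raw` and `status`; otherwise the raw p-value
#'   vector in original gene order.
#' @export
screen_genes <- function(snapshot, matrix, details = FALSE) {
  stopifnot(inherits(snapshot, "survival_snapshot"), is.matrix(matrix))
  d <- nrow(matrix)
  if (snapshot$n == 0) {
    warning("empty snapshot: no patients arrived yet; returning p = 1 for all genes")
    fit <- list(beta = rep(NA_real_, d), se = rep(NA_real_, d),
                p = rep(1, d), status = rep("degenerate", d))
  } else {
    x <- align_expr(snapshot, matrix)
    fit <- cox_fit_matrix(snapshot$time, snapshot$event, x)
  }
  if (!details) return(fit$p)
  data.frame(gene_id = if (is.null(rownames(matrix)))
               paste0("g", seq_len(d)) else rownames(matrix),
             beta_hat = fit$beta, se = fit$se, p_raw = fit$p,
             status = fit$status, stringsAsFactors = FALSE)
}

align_expr <- function(snapshot, matrix) {
  if (ncol(matrix) == snapshot$n) return(matrix)
  if (ncol(matrix) >= max(snapshot$index))
    return(matrix[, snapshot$index, drop = FALSE])
  stop("expression matrix has ", ncol(matrix),
       " columns; cannot cover the snapshot's included patients")
}

# Vectorized Breslow-Cox Newton solver over the rows of X.
# time/event: per-patient observed times and event indicators (snapshot
# scale); X: d x n, columns aligned to patients.  Zero-length records
# (arrival exactly at the analysis time) are dropped here.
cox_fit_matrix <- function(time, event, X,
                           max_iter = 30L, tol = 1e-10, beta_cap = 15) {
  d <- nrow(X)
  out <- list(beta = rep(NA_real_, d), se = rep(NA_real_, d),
              p = rep(1, d), status = rep("degenerate", d))

  keep <- time > 0
  time <- time[keep]; event <- event[keep]
  X <- X[, keep, drop = FALSE]
  n <- length(time)
  if (n == 0L || sum(event) < 2L) return(out)

  ord <- order(time)
  y <- time[ord]
  Xs <- X[, ord, drop = FALSE]
  ev <- event[ord] == 1L
  # Breslow risk sets: events at tied times share the risk set of the
  # first (smallest-index) member of the tie group in sorted order.
  first <- match(y, y)
  evi <- which(ev)
  f <- first[evi]
  xev_sum <- rowSums(Xs[, evi, drop = FALSE])

  ctr <- rowMeans(Xs)
  const <- rowSums((Xs - ctr)^2) == 0
  act <- which(!const)
  if (length(act) == 0L) return(out)

  suffix_sums <- function(M) {
    nc <- ncol(M)
    if (nc > 1L) for (j in (nc - 1L):1L) M[, j] <- M[, j] + M[, j + 1L]
    M
  }
  # log-partial-likelihood, score and information for the genes in `rows`
  quant <- function(b, rows) {
    Xa <- Xs[rows, , drop = FALSE]
    E <- exp(Xa * b)
    S0 <- suffix_sums(E)[, f, drop = FALSE]
    S1 <- suffix_sums(E * Xa)[, f, drop = FALSE]
    S2 <- suffix_sums(E * Xa * Xa)[, f, drop = FALSE]
    m1 <- S1 / S0
    list(ll = xev_sum[rows] * b - rowSums(log(S0)),
         U = xev_sum[rows] - rowSums(m1),
         I = rowSums(S2 / S0 - m1 * m1))
  }

  beta <- numeric(d)
  U_fin <- I_fin <- rep(NA_real_, d)
  q0 <- quant(rep(0, length(act)), act)
  # no contrast within any risk set => flat likelihood
  flat <- q0$I <= 1e-12
  if (any(flat)) {
    act <- act[!flat]
    q0 <- lapply(q0, function(v) v[!flat])
  }
  score_z <- rep(NA_real_, d)
  score_z[act] <- q0$U / sqrt(q0$I)

  cur <- act           # still-active gene indices
  q <- q0
  for (it in seq_len(max_iter)) {
    if (length(cur) == 0L) break
    step <- q$U / q$I
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -2), 2)
    ll_old <- q$ll
    for (h in 0:4) {
      bnew <- pmin(pmax(beta[cur] + step, -beta_cap), beta_cap)
      qn <- quant(bnew, cur)
      bad <- is.finite(ll_old) & (qn$ll < ll_old - 1e-9) & h < 4
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    beta[cur] <- bnew
    U_fin[cur] <- qn$U; I_fin[cur] <- qn$I
    done <- abs(step) < tol * (1 + abs(bnew)) | abs(bnew) >= beta_cap
    if (any(done)) {
      cur <- cur[!done]
      q <- lapply(qn, function(v) v[!done])
    } else q <- qn
  }

  ok <- setdiff(act, cur)
  ok <- ok[abs(beta[ok]) < beta_cap & I_fin[ok] > 0]
  fb <- setdiff(act, ok)
  if (length(ok)) {
    out$beta[ok] <- beta[ok]
    out$se[ok] <- 1 / sqrt(I_fin[ok])
    out$p[ok] <- 2 * stats::pnorm(-abs(beta[ok] / out$se[ok]))
    out$status[ok] <- "ok"
  }
  if (length(fb)) {
    out$beta[fb] <- beta[fb]
    out$p[fb] <- 2 * stats::pnorm(-abs(score_z[fb]))
    out$status[fb] <- "fallback"
  }
  out
}

#' Write a per-analysis p-value table
#'
#' Delimited text with columns `gene_id`, `beta_hat`, `se`, `p_raw`,
#' `p_adjusted`.
#'
#' @param details data.frame from `screen_genes(..., details = TRUE)`.
#' @param p_adjusted BH-adjusted p-values, e.g. from [bh_adjust()].
#' @param path output file path (extension selects the delimiter).
#' @export
write_pvalue_table <- function(details, p_adjusted, path) {
  stopifnot(nrow(details) == length(p_adjusted))
  df <- details[, c("gene_id", "beta_hat", "se", "p_raw")]
  df$p_adjusted <- p_adjusted
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
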