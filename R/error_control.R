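#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the classical step-up adjusted p-values: with raw p-values sorted
#' ascending, q_(k) = min over j >= k of min(1, d * p_(j) / j), mapped back
#' to the original order.  Rejecting all genes with adjusted p <= alpha is
#' exactly the BH procedure at FDR level alpha.  The p-values from every
#' interim look are adjusted at the full nominal level: no interim-specific
#' alpha-spending is applied, which for large gene counts leaves the FDR
#' controlled at each look.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param by if `TRUE`, apply the stricter Benjamini-Yekutieli variant
#'   (the nominal level is effectively divided by sum(1/i)); off by
#'   default.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.001, 0.2, 0.9))  # 0.003 0.300 0.900
#' @export
bh_adjust <- function(p, by = FALSE) {
  stopifnot(all(p >= 0 & p <= 1))
  d <- length(p)
  if (d == 0L) return(numeric(0))
  o <- order(p)               # stable: ties keep original order
  cm <- if (by) sum(1 / seq_len(d)) else 1
  q <- pmin(1, cm * d * p[o] / seq_len(d))
  q <- rev(cummin(rev(q)))
  q[order(o)]
}

#' Equivalent raw-p-value threshold of the BH procedure
#'
#' Finds the largest k with p_(k) <= (k/d) * alpha and returns the adjusted
#' alpha-level alpha^BH = (k/d) * alpha; rejecting all raw p-values <=
#' alpha^BH reproduces the BH rejection set.  Returns 0 when no k
#' qualifies (so that nothing is rejected at the raw scale either).
#'
#' @param p numeric vector of raw p-values.
#' @param alpha nominal FDR level.
#' @return the scalar alpha^BH.
#' @examples
#' bh_alpha(c(0.001, 0.2, 0.9), 0.05)  # 0.05/3
#' @export
bh_alpha <- function(p, alpha) {
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  d <- length(p)
  ps <- sort(p)
  k <- which(ps <= seq_len(d) / d * alpha)
  if (length(k) == 0L) return(0)
  max(k) / d * alpha
}

#' Confusion counts and truth-aware error/power metrics
#'
#' Compares a rejection set with the known truth of a simulated effect
#' vector.  The false discovery proportion is FDP = FP / R, defined as 0
#' when R = 0; the true average power rate is APR = TP / d1, defined as 0
#' when d1 = 0.
#'
#' @param reject integer vector of rejected gene indices (subset of 1..d).
#' @param truth an [build_effect_vector()] result.
#' @return A list of class `test_decision_summary` with `R`, `FP`, `TP`,
#'   `FN`, `TN`, `FDP`, `APR_true`.
#' @export
confusion_metrics <- function(reject, truth) {
  stopifnot(inherits(truth, "effect_vector"))
  reject <- as.integer(reject)
  if (length(reject) && (min(reject) < 1L || max(reject) > truth$d))
    stop("reject indices must lie in 1..d")
  R <- length(reject)
  TP <- sum(reject %in% truth$alt_set)
  FP <- R - TP
  d1 <- truth$d1; d0 <- truth$d - d1
  structure(list(R = R, FP = FP, TP = TP,
                 FN = d1 - TP, TN = d0 - FP,
                 FDP = if (R > 0) FP / R else 0,
                 APR_true = if (d1 > 0) TP / d1 else 0),
            class = "test_decision_summary")
}

#' @export
print.test_decision_summary <- function(x, ...) {
  cat(sprintf("R = %d (TP %d, FP %d); FDP = %.4f; true APR = %.4f\n",
              x$R, x$TP, x$FP, x$FDP, x$APR_true))
  invisible(x)
}
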