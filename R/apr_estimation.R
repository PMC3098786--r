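#' Estimate the fraction of true null genes (pi0)
#'
#' Plug-in estimator based on the uniformity of null p-values: p-values
#' above a threshold theta belong "mostly" to true nulls, so
#' pi0_hat = #\{p_i > theta\} / ((1 - theta) * d).  theta trades bias (small
#' theta contaminates the tail with alternatives) against variance (large
#' theta leaves few p-values); theta = 0.5 is a good default in the regimes
#' this package simulates.  The estimate is clipped to (1/d, 1] so that the
#' implied alternative count d1_hat = d * (1 - pi0_hat) stays below d and
#' downstream denominators stay finite.
#'
#' @param p numeric vector of raw p-values.
#' @param theta tail threshold in (0, 1).
#' @return scalar pi0 estimate in (0, 1].
#' @examples
#' estimate_pi0(runif(1000))  # close to 1 under the global null
#' @export
estimate_pi0 <- function(p, theta = 0.5) {
  stopifnot(length(p) > 0, theta > 0, theta < 1)
  d <- length(p)
  pi0 <- sum(p > theta) / ((1 - theta) * d)
  min(max(pi0, 1 / d), 1)
}

#' Smoother-based pi0 estimate
#'
#' The bias of the fixed-theta estimator vanishes as theta -> 1 while its
#' variance explodes; the smoother variant evaluates pi0_hat(theta) on the
#' grid theta = 0, 0.05, ..., 0.90, fits a cubic smoothing spline, and takes
#' the smoothed value at the right end of the grid.  If the spline cannot be
#' fitted (degenerate p-value vectors) the fixed estimator at theta = 0.5 is
#' used with a warning.
#'
#' @param p numeric vector of raw p-values.
#' @return scalar pi0 estimate in (0, 1].
#' @export
estimate_pi0_smoother <- function(p) {
  stopifnot(length(p) > 0)
  d <- length(p)
  if (length(unique(p)) == 1L) {
    warning("pi0 smoother fit degenerate; falling back to theta = 0.5")
    return(estimate_pi0(p, 0.5))
  }
  grid <- seq(0, 0.90, by = 0.05)
  pi0g <- vapply(grid, function(th) sum(p > th) / ((1 - th) * d), numeric(1))
  fit <- tryCatch(stats::smooth.spline(grid, pi0g, df = 3),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("pi0 smoother fit degenerate; falling back to theta = 0.5")
    return(estimate_pi0(p, 0.5))
  }
  pi0 <- stats::predict(fit, x = 0.90)$y
  min(max(pi0, 1 / d), 1)
}

#' Plug-in estimate of the achieved average power rate (APR)
#'
#' The APR is the proportion of truly survival-related genes that the
#' current look detects, TP / d1.  Neither TP nor d1 is observable, so both
#' are estimated from the p-value distribution: R rejections stand in for
#' E[R]; the expected false positives among them are fp_hat =
#' pi0_hat * d * alpha', where alpha' is the raw-scale rejection threshold
#' (here alpha^BH, the data-dependent BH threshold); and the alternative
#' count is d1_hat = d * (1 - pi0_hat).  The estimate
#' (R - fp_hat) / d1_hat is clipped to `[0, 1]` and forced to 0 whenever
#' R = 0 (a look that rejects nothing cannot claim power; alpha^BH = 0
#' there, so fp_hat = 0 as well).
#'
#' @param p numeric vector of raw p-values.
#' @param alpha nominal FDR level used for the BH rejection.
#' @param pi0_method `"fixed-theta"` (default) or `"smoother"`.
#' @param theta tail threshold for the fixed-theta pi0 estimator.
#' @return A list of class `apr_estimate` with `pi0_hat`, `alpha_prime`,
#'   `fp_hat`, `d1_hat`, `apr_hat`, `R`, `variant`.
#' @examples
#' p <- c(rbeta(300, 0.2, 5), runif(700))
#' estimate_apr(p, alpha = 0.05)
#' @export
estimate_apr <- function(p, alpha,
                         pi0_method = c("fixed-theta", "smoother"),
                         theta = 0.5) {
  pi0_method <- match.arg(pi0_method)
  stopifnot(alpha > 0, alpha < 1)
  d <- length(p)
  R <- sum(bh_adjust(p) <= alpha)
  alpha_prime <- if (R > 0) bh_alpha(p, alpha) else 0
  pi0 <- if (pi0_method == "fixed-theta") estimate_pi0(p, theta)
         else estimate_pi0_smoother(p)
  structure(c(list(pi0_hat = pi0, alpha_prime = alpha_prime),
              apr_plugin(R, pi0, alpha_prime, d),
              list(R = R, variant = pi0_method)),
            class = "apr_estimate")
}

# estimator arithmetic: fp_hat = pi0 * d * alpha', d1_hat = d * (1 - pi0),
# apr_hat = (R - fp_hat) / d1_hat clipped to [0,1]; 0 when R = 0 or
# d1_hat <= 0
apr_plugin <- function(R, pi0, alpha_prime, d) {
  fp_hat <- pi0 * d * alpha_prime
  d1_hat <- d * (1 - pi0)
  apr <- if (R == 0 || d1_hat <= 0) 0
         else min(max((R - fp_hat) / d1_hat, 0), 1)
  list(fp_hat = fp_hat, d1_hat = d1_hat, apr_hat = apr)
}

#' @export
print.apr_estimate <- function(x, ...) {
  cat(sprintf(
    "APR estimate (%s): R = %d, pi0_hat = %.3f, fp_hat = %.1f, d1_hat = %.1f, apr_hat = %.3f\n",
    x$variant, x$R, x$pi0_hat, x$fp_hat, x$d1_hat, x$apr_hat))
  invisible(x)
}

#' Early-stopping decision
#'
#' The study stops at the first look whose estimated APR reaches the
#' pre-specified threshold.  The comparison is inclusive (`>=`) so that a
#' threshold of 1 is attainable; set `strict = TRUE` for a strict `>`.
#'
#' @param estimate an [estimate_apr()] result (or a bare apr value).
#' @param threshold stop level in (0, 1].
#' @param strict use strict inequality.
#' @return logical: `TRUE` to stop.
#' @export
check_stop <- function(estimate, threshold, strict = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  apr <- if (inherits(estimate, "apr_estimate")) estimate$apr_hat
         else as.numeric(estimate)
  if (strict) apr > threshold else apr >= threshold
}

#' Total alternative count implied by a rejection count and an APR estimate
#'
#' Inverts the APR definition APR = TP / d1 under the approximation
#' TP ~= R: given R detected genes at an estimated power of `apr_hat`, the
#' implied number of survival-related genes in the data is R / apr_hat.
#' Useful to transfer a power estimate from a real data set into a
#' simulation parameterization.
#'
#' @param R rejection count.
#' @param apr_hat estimated APR in (0, 1].
#' @return implied d1 (not rounded).
#' @examples
#' implied_d1(1900, 0.27)  # about 7037
#' @export
implied_d1 <- function(R, apr_hat) {
  stopifnot(R >= 0, apr_hat > 0, apr_hat <= 1)
  R / apr_hat
}
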