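---
title: "Interim analyses of gene-wise survival screens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interim analyses of gene-wise survival screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microarray survival studies correlate pretherapeutic gene-expression
profiles with patient survival to find prognostic biomarkers, typically by
fitting a Cox proportional-hazards model per gene.  Because recruitment and
follow-up take years, there is a strong incentive to look at the data
before the planned end: an interim analysis can justify stopping early, or
at least starting laboratory validation of the detected genes.  Classical
group-sequential methodology spends the type-I error over the planned looks
and tests at reduced interim levels, but it was developed for a single
endpoint.  With thousands of genes the situation changes qualitatively:
when the false discovery rate (FDR) is the error criterion and the number
of tests is large, repeated Benjamini--Hochberg (BH) testing at the full
nominal level leaves the per-look FDR controlled, so no interim-specific
alpha-spending is needed.  `survinterim` provides a simulation framework
for exactly this setting -- to check the error-rate behaviour of a planned
design, to study the build-up of power over the looks, and to evaluate an
early-stopping rule -- plus the same per-look pipeline for real data.

## Study design

A study has `N` patients arriving uniformly over an intended recruitment
window of `l1` months, followed by `l2` months of follow-up with no new
entries.  `M1` analyses are scheduled during recruitment, one each time
`N/M1` new samples have accrued (so look `m` happens at the arrival of
patient `round(m * N / M1)` in arrival order, round half up), and `M2`
analyses at equally spaced calendar times during follow-up.  The actual
recruitment length is the last arrival, `l1 = max(a)`, and the follow-up
looks anchor there, the final one at `l1 + l2`.

Every look uses *all* accumulated data: the snapshot at calendar time `t`
contains every patient with arrival `a_j <= t`, with observed time
`min(s_j, t - a_j)` and an event indicator for deaths that have already
happened.  Censoring is purely administrative.  A patient arriving exactly
at `t` is included with an observed time of zero; such records carry no
risk-set information and are dropped again inside the Cox fit.  (Neither
convention is forced by the design; this one avoids degenerate likelihood
terms while keeping the snapshot a pure function of `t`.)

## Gene-wise screening

Gene `i` is screened with the univariate Cox model
`h(t | x_i) = h0(t) exp(beta_i x_ij)`; the baseline hazard `h0` is profiled
out by the partial likelihood and never estimated.  `H0i: beta_i = 0` gets
a two-sided Wald p-value.  Numerical choices, all of which matter only in
corner cases:

* **Ties**: Breslow.  Simulated survival times are continuous, so ties are
  measure-zero there; on real data Breslow is deterministic and simple.
* **Maximization**: Newton iteration shared across all genes of a look
  (the risk-set structure is computed once, so a full screen is a handful
  of matrix operations per iteration), at most 30 iterations, steps capped
  at 2 with step-halving whenever the log-likelihood would decrease, and
  `|beta|` capped at 15.
* **Degenerate looks**: fewer than 2 events, or a gene constant across the
  included patients, give `p = 1` (status `degenerate`).  Early looks of a
  realistic design are full of these.
* **Separation**: with very few events a gene can order perfectly with the
  death times and the partial likelihood becomes monotone in `beta`
  (no interior maximizer).  Such fits, and any non-converged ones, report
  the score test at `beta = 0` instead (status `fallback`), which stays
  well-behaved under separation.
* The Wald/score choice is a convention; the tests agree asymptotically
  and standard Cox software of the microarray era reported Wald by
  default.

## Error control across looks

At each look the raw p-values are BH-adjusted and compared with the full
nominal level `alpha` -- the same level at every look.  The equivalent
raw-scale threshold `alpha^BH` (the largest `(k/d) alpha` with
`p_(k) <= (k/d) alpha`, 0 if none) is carried along because the power
estimator needs it.  The false discovery proportion `FDP = FP/R` and the
FDR are defined as 0 when `R = 0`.  A stricter Benjamini--Yekutieli switch
is available but off by default.  Against the simulation truth the package
also reports the *average power rate* `APR = TP/d1`, the detected fraction
of the `d1` truly survival-related genes (0 when `d1 = 0`).

## Estimating the achieved power

The APR is estimated from observable quantities only:

* `pi0_hat = #{p_i > theta} / ((1 - theta) d)` estimates the true-null
  fraction from the upper tail of the p-value distribution, where null
  p-values are uniform.  `theta` trades bias (alternatives contaminating
  the tail) against variance; the default is `theta = 0.5`.  A smoother
  variant evaluates the estimator on the grid `theta = 0, 0.05, ..., 0.90`,
  fits a cubic smoothing spline and reads it off at the right end, since
  the bias vanishes as `theta -> 1`.
* `fp_hat = pi0_hat * d * alpha'` estimates the false positives among the
  `R` rejections, with `alpha' = alpha^BH` as the raw-scale threshold
  actually applied.
* `d1_hat = d (1 - pi0_hat)` estimates the alternative count, and
  `apr_hat = (R - fp_hat) / d1_hat`, clipped to `[0, 1]`.

Two guards are deliberate: `pi0_hat` is clipped to `(1/d, 1]` so `d1_hat`
stays positive and below `d`; and `apr_hat = 0` whenever `R = 0` -- a look
that rejects nothing cannot claim power.  The second rule also removes a
known artefact of the estimator chain, where a zero-rejection look can
otherwise produce a visibly nonzero power estimate from the tail shape
alone.  The study stops at the first look with `apr_hat >=` the threshold
(inclusive, so a threshold of 1 is attainable; a strict mode exists).
During simulation, stopping is *recorded, not enforced*: all `M` looks of
every run are computed, which lets one summary serve both the per-look
error/power tables and the first-stop distribution.

## The synthetic world

The generator states one specific world; its defaults are fixed and not
revisited per experiment:

* Arrivals `Uniform(0, l1)` with `l1 = 60` months; survival exponential
  with mean `lambda = 60` months; `N = 50`.  Patients with `s < lambda`
  form the short-survivor group, the rest the long-survivor group (for the
  log-normal family the split is at the distribution median).
* Expression for `d` genes is multivariate normal within each group with
  a common AR(1) covariance `Sigma_ik = sigma2 * rho^|i-k|` -- strong
  local correlation, distant independence.  The numeric entries are not
  fixed by the reference design, so the package defaults to `rho = 0.5`,
  `sigma2 = 1` (both configurable).  Sampling uses the sequential AR(1)
  construction, which is `O(d n)` and exactly equivalent to a dense
  Cholesky draw (verified against one in the tests).
* The long-survivor group mean is shifted by `mu2`, nonzero for a fraction
  `tau` of randomly chosen genes (`tau = 0.5` by default), drawn from a
  normal and rounded to a discretization grid; zero-rounded draws are
  redrawn so the declared `tau` is exact.  This encodes the biological
  stylization that a gene is either regulated or not -- direction, not
  strength, distinguishes the groups.

**Effect-size calibration.**  The reference design prints its fold-change
distributions only graphically, so the package had to choose them.  The
"large" regime was calibrated -- once -- so that the final-look true APR
of the `tau = 50%`, `M = 4` design is about 0.8, and is `sd = 1.5` on a
grid of width `1.0`.  The grid width matters as much as the scale: a fine
grid with a large `sd` produces many alternatives too weak ever to be
detected, and those contaminate the upper p-value tail, bias `pi0_hat`
upward and inflate `apr_hat` by ~0.07 in that design, which contradicts
the near-agreement of estimated and true APR this regime is supposed to
show.  A coarse grid makes every alternative at least one marginal SD in
size and keeps the tail clean (estimator gap ~0.01).  The "small" regime
is `sd = 0.8` on a grid of `0.5`.  A consequence worth knowing: per-look
power at the *interim* looks is only anchored indirectly, and quantities
that threshold it sharply (such as the mean first-stop index under an 80%
rule, which sits near the look-3/look-4 boundary) are sensitive to this
residual freedom.
* The breast-cancer-parameterized profile instead takes the mean-shift
  multiset from a packaged value/count table (24496 genes, 8542 nonzero,
  grid width 0.04), log-normal survival with median 84 months
  (`meanlog = log(84)`; `sdlog = 0.8` is a package choice, as the fitted
  scale is not published), `sigma2 = 0.1` (the stated ten-fold variance
  reduction), recruitment 132 months, and follow-up 84 months (also a
  package choice; only the recruitment length is published).

**What the generator does not emulate**: microarray noise (probe effects,
batch and normalization artefacts -- in particular the re-normalization
inconsistencies that real interim analyses would face), non-normal
expression marginals, informative or drop-out censoring, and non-uniform
accrual.  A green simulation therefore establishes the *statistical*
behaviour of the per-look pipeline under the stated world, not robustness
to array-technology artefacts.

## Reproducibility and scale

Run `r` of a Monte-Carlo summary seeds its own RNG stream with
`base_seed + r`, so runs are reproducible individually and independent of
execution order; a whole run is bit-identical given `(config, run_seed)`.
The package's test defaults scale the reference designs down to
`d = 2000` genes and 200 runs (the full scale, `d = 10000` and 1000 runs,
is available through `profile_config()` unmodified); means of FDP and APR
are insensitive to this because the BH identity `E[FDP] ~ pi0 * alpha`
and the per-gene power do not depend on `d`, while extreme-tail quantities
(the very first rejections of a look) do vary slightly with `d`.

## Known limitations

* The Langaas-type nonparametric `pi0` estimator and beta-uniform-mixture
  APR variant are not implemented; the estimator interface accepts the two
  provided variants (`fixed-theta`, `smoother`) only.
* FDR-based or gene-count-based stopping criteria, survival models with
  time-varying effects, and multivariate screening are out of scope.
* `bh_adjust` controls the FDR under independence and positive regression
  dependence; under the AR(1) world this holds in simulation, but
  arbitrary dependence would need the BY switch.
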