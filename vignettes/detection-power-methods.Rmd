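---
title: "Methods: the two-step detection model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-step detection model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by clonopower,
the numerical choices behind it, and what the synthetic spike-in
generator does and does not emulate.

## The two-step read-count model

The probability of detecting a target TCR clonotype in a bulk sequencing
experiment is modelled in two stages.

**Stage 1 — blood sampling.** A sample of `T_samp` T cells is an
(assumed perfectly even) subsample of the body's T-cell population, so
the number of target cells in it is Poisson,

    C_samp ~ Poisson(f_body * T_samp),

with `f_body` the clonotype frequency in the body. One receptor per cell
is assumed throughout, so "cells" and "TCRs" are interchangeable in
`T_samp`. Homogeneous mixing is reasonable for peripheral blood; for
tissue biopsies with local clonal expansions the Poisson assumption can
fail, and the package makes no attempt to model that.

**Stage 2 — sequencing.** Conditional on `C_samp`, the in-sample
frequency is `f_samp = C_samp / T_samp`, and the read count is negative
binomial with a power-law mean–variance relationship:

    C_read ~ NB(mu, sigma^2),  mu = f_samp * r_e * T_read,
    sigma^2 = mu + eta * mu^lambda.

The three method parameters are:

* `r_e` (read efficiency, dimensionless, in [0, 1]): the proportionality
  between `f_samp * T_read` and the expected read count. Losses during
  library preparation push it below 1.
* `eta` (overdispersion scale, ≥ 0): excess variance beyond Poisson,
  attributable to PCR and library chemistry. `eta = 0` is exact Poisson
  subsampling.
* `lambda` (mean–variance exponent): how overdispersion scales with
  expression level. `lambda = 2` would be a constant coefficient of
  variation; fits on spike-in data typically land near 1.3.

The negative binomial is parameterised through
`size = mu^(2 - lambda) / eta` with success probability
`size / (size + mu)`, using the continuous (gamma-function) pmf since
`size` is rarely an integer. When `size` exceeds 1e12 the overdispersion
term is below double precision resolution and the Poisson pmf is used;
when it underflows (variance astronomically large) an error is raised
rather than returning garbage.

**Marginalisation.** `C_samp` is unobserved, so the read-count
distribution is

    P(C_read) = sum_c P2(C_read | C_samp = c) P1(C_samp = c),

and detection power at read threshold `c_thresh` is
`P(C_read > c_thresh)`. The `c_samp = 0` term (which contributes only to
`C_read = 0`) is always included, so the marginal pmf normalises to 1
and power calculations are unaffected by it. Inside each term the
threshold sum is evaluated as the negative-binomial survival function,
which is algebraically identical to summing the conditional pmf from 0
to `c_thresh` but stable for thresholds far from the mean.

## Numerical choices

* **Truncation of the Poisson sum.** The `c_samp` sum runs over a window
  `mean ± 10 sd`, widened to the 1e-14 / 1 - 1e-14 Poisson quantiles
  (the quantile bound matters at small rates, where `mean + 10 sd` alone
  leaves ~1e-11 of tail mass), and terms whose Poisson weight is below
  1e-16 of the largest weight are dropped. All three settings are
  exposed via `marginal_control()`. The neglected mass is below ~1e-13,
  comfortably inside the 1e-10 agreement the tests demand against
  closed forms and brute-force double summation.
* **Log-space pmfs.** All pmf terms are computed in log space and
  combined by log-sum-exp; probabilities are exponentiated only at the
  interface.
* **Root finding.** `detection_limit()` and `min_detectable_fbody()`
  exploit strict monotonicity of detection probability in the frequency
  and bisect on `log f` (relative tolerance 1e-6 on `f`, 1e-4 on the
  achieved power). If even `f = 1` cannot reach the requested
  probability, an error reports the maximum achievable value rather
  than returning a boundary root.
* **Grid evaluation.** `power_grid()` computes the truncated Poisson
  weight vector once per `(f_body, t_samp)` row and reuses it across
  the read-depth axis. The 0.95 contour is extracted by linear
  interpolation of power on the log read-depth axis.

## Calibration

`fit_read_model()` maximises the Component-2 likelihood
`sum_i log P(c_read_i | mu_i, sigma_i^2)` over the spike-in observations
(`mu_i = f_samp_i * r_e * T_read`); blood sampling plays no role because
the spike-in sample frequencies are known. Each chain × experiment-set
combination should be calibrated separately, with that set's total chain
read count as `T_read`.

Design of the optimiser:

* Parameters are transformed — logit `r_e`, log `eta`, `lambda` boxed in
  `[0.5, 3]` by default — and optimised with L-BFGS-B, avoiding
  constrained-optimiser fragility at the boundaries.
* The likelihood can be multimodal in `(eta, lambda)`, so optimisation
  is multi-start: a method-of-moments start (ratio estimate of `r_e`;
  regression of log excess variance on log mean across frequency tiers
  for `eta`, `lambda`) plus a fixed 3 × 3 grid of `(eta, lambda)`
  values. At least three distinct spike-in frequencies are required,
  otherwise `lambda` is unidentifiable and the fit refuses to run.
* **Boundary model selection.** When the data carry no excess variance,
  `eta` and `lambda` are unidentified and the MLE drifts along a flat
  ridge near `eta = 0`. An explicit Poisson (`eta = 0`) submodel is
  therefore fitted alongside, and selected unless the negative binomial
  improves the log-likelihood by more than 2 — the AIC criterion for
  its two extra parameters.
* The parameter covariance comes from the numeric Hessian on the
  transformed scale, mapped to the natural scale by the delta method;
  zero-count observations of retained spike-ins stay in the likelihood.

**Detection-limit confidence intervals.** `detection_limit_ci()` uses a
seeded parametric bootstrap: `n_boot` (default 1000) parameter vectors
drawn from the multivariate normal at the MLE, truncated to the feasible
box (`r_e` in (0, 1], `eta ≥ 0`), each mapped through the
detection-limit solver, summarised by 2.5/97.5 percentiles. A Wald
(delta-method) interval on `log f` is available as `method = "wald"`.
The bootstrap is the package's own construction; intervals from other
CI constructions on the same data may differ somewhat.

## Monotonicity: one caveat

Detection power is monotone non-decreasing in `f_body`, `T_read` and
`r_e`, and non-increasing in `c_thresh` and (empirically) `eta`. In
`T_samp` it is monotone **only when the read threshold is below the
expected read count**: at `c_thresh = 0` monotonicity is a Jensen-type
consequence of the conditional zero probability being convex in
`C_samp`, and the tests assert it there. When
`c_thresh > f_body * r_e * T_read`, detection relies on upward count
fluctuations, which a larger (less noisy) sample suppresses — power can
then genuinely *decrease* with `T_samp` (e.g. `f_body = 1e-4`,
`c_thresh = 18`, `T_read = 1e5`). This regime sits in the deep-red,
low-power corner of practical power grids; within the useful region the
familiar rectangular-with-rounded-corner 95% contour emerges, whose
crossing index the tests check instead.

## The synthetic spike-in generator

`generate_spikein_experiment()` emulates the structure of a titrated
spike-in calibration experiment:

* 9 frequency tiers (1, 3, 10, 50, 300, 1000, 3000, 10000, 50000 per
  million) × 5 clones per tier = 45 spike-in clones, 6 replicates, TRA
  and TRB chains — all configurable via `spikein_design()`.
* Random distinct CDR3 nucleotide sequences (lengths 24–60, multiples
  of 3, so the IMGT trim always leaves a long core).
* Read counts drawn from the gamma–Poisson mixture form of the
  negative binomial (shape `mu^(2 - lambda) / eta`), which corresponds
  exactly to `negbin_read_pmf()`; counts are independent across clones,
  so replicate totals fluctuate around `t_read`. An `exact_totals`
  mode rescales each replicate to exactly `t_read` by a multinomial
  redraw, supporting frequency-sum checks.
* A background repertoire of unknown clonotypes with power-law
  rank-frequency distribution (default exponent 2, 400 clones),
  mimicking the long-tailed in-vivo frequency distribution.
* Optional planted artefacts: fully-dropped-out clones, a
  spike-in-only control set, control-exclusive low-count false
  positives, and index-hopping false positives leaking from the
  background at ~1% of their source counts (the 1–2-logs-lower linear
  trend characteristic of patterned-flow-cell index hopping).

What it does **not** emulate: V/J segment structure, sequencing-error
base substitutions, PCR-cycle mechanics, or chain-specific transcript
abundance differences. Passing tests therefore demonstrate that the
estimator and pipeline recover the model's own structure under
realistic sizes and noise — not that any particular laboratory protocol
follows this model; that is what real spike-in pilot data and
recalibration are for.

A note on the dropout-exclusion fixtures: at the study-like depth of
1e6 reads, the lowest tier (1 per million, `mu ≈ 0.7`) drops out of
entire replicate sets by chance — the same phenomenon that removes
spike-ins from real experiments. Tests that require *exact* recovery of
planted dropouts therefore use a depth of 2e7 reads (lowest-tier
`mu ≈ 14`, natural full-dropout probability ~4e-4); tests of the
exclusion rule itself use the study depth.

## Problem sizes used by the test suite

Parameter-recovery and coverage checks run the full study design
(9 × 5 × 6 = 270 observations, `T_read = 1e6`) across 50 seeded
replications, with 95% intervals from 400 multivariate-normal draws per
fit; brute-force oracle comparisons use 50 randomised small instances
with `T_samp ≤ 100`; Monte-Carlo moment checks use 1e5 draws with
3-standard-error bands. These sizes make the whole suite run in well
under a minute per file while leaving the statistical assertions sharp.

## Other conventions and limitations

* Dispersion index uses the sample (n − 1) standard deviation over the
  mean; frequency-accuracy R² is computed on log10–log10 axes over
  detected points only (zeros are untransformable; their count is
  reported).
* Duplicate library pairs (set labels differing in a trailing `a`/`b`)
  are merged by summing raw counts before frequencies are computed.
* Spike-in matching is exact nucleotide identity per chain after IMGT
  trimming; no fuzzy matching.
* The undetected-spike-in exclusion rule treats failure of either chain
  as excluding the whole clone from TCR-level analyses (`by = "tcr"`),
  with a chain-level alternative (`by = "chain"`) for chain-wise
  calibration.
* False positives whose control count exceeds the largest spike-in
  count are flagged as outliers and reported, never silently dropped.
* No family-wise or FDR extension over sets of clonotypes is provided;
  calibration requires ground-truth spike-in data by construction.
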