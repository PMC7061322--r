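---
title: "Modelling navigational learning and its microstructural correlates with navlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling navigational learning and its microstructural correlates with navlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navlearn)
```

## The estimation problem

In a virtual Morris Water Maze, the time to find a hidden goal falls
across trials, but participants differ both in how fast they learn and
in how they behave once the environment is learned: many reach a
plateau well before the final trial and then show variable — sometimes
slow — late-trial performance, through fatigue, lapses of motivation or
exploration. A curve fitted to *all* trials therefore punishes exactly
the fastest learners, whose post-plateau trials fit a monotone model
worst.

`navlearn` estimates a per-participant learning rate in two stages:

1. **Cut-off.** An ordinary least-squares second-order polynomial
   `c0 + c1·x + c2·x²` is fitted to all latencies. When the parabola
   opens upward (`c2 > 0`) and its trough `-c1/(2·c2)` — where the first
   derivative crosses zero — lies inside `[4, n]`, the cut-off is the
   trough rounded half-up to the nearest trial. Otherwise there is no
   interior trough, nothing to trim, and all trials are used. The lower
   bound 4 guarantees the two-parameter power fit that follows retains
   residual degrees of freedom.
2. **Power fit.** Trials `1..cutoff` are fitted with `T = a·x^b`. The
   default method regresses `log T` on `log x` (closed form,
   deterministic, and what a log–log plot displays); `b` is the slope,
   `a` the back-transformed intercept, and R² is reported on the
   fitting (log–log) scale. An optional `nonlinear_ls` method refines
   `(a, b)` by Levenberg–Marquardt least squares on the raw scale
   (`minpack.lm`), reporting raw-scale R²; the method used is recorded
   in every result. Whether the original analyses computed R² on the
   raw or log scale is not documented anywhere we could check, so both
   are available and the deterministic one is the default.

`mean_latency_to_cutoff()` provides the non-slope alternative measure
(the plain mean of latencies to the cut-off), usable also for
participants who fail the behavioural screen below.

Two exact invariances pin down the arithmetic and are enforced by the
test suite: the cut-off is invariant under positive affine transforms
of latency, and rescaling latencies by `k` multiplies `a` by `k` while
leaving `b` and log-scale R² untouched.

Degenerate inputs are handled explicitly: a flat series has slope 0 and
R² defined as 0 (the usual 0/0 is resolved to "no variance explained");
timeout trials enter at the 60 s ceiling with no censoring adjustment,
matching a task in which the goal is revealed at timeout; missing
trials are rejected at I/O rather than imputed.

## Behavioural screening

Rather than excluding "poor performers" by an arbitrary latency
criterion, a participant is excluded when their fit statistic is
indistinguishable from trial-order chance. The trial labels of the
participant's own latencies are shuffled `n_perm = 500` times and the
fit statistic recomputed per shuffle. Two statistic definitions are
offered because the procedure is ambiguous in prose descriptions of
this design:

* `"full"` (default): re-derive the quadratic cut-off, then fit — the
  null statistic has the same definition as the observed one;
* `"all_trials"`: a power fit to all trials per shuffle.

The threshold is the empirical 84th percentile of the null — the upper
edge of its central 68% interval, the distribution-free reading of a
"1 SD" criterion; a `mean_plus_sd` variant is selectable. Exclusion is
`true R² ≤ threshold`. Under exchangeable (trend-free) latencies the
observed statistic is itself a draw from the null, so the screen
excludes almost exactly 84% of true non-learners — a calibration
property the acceptance suite verifies with 2,000 simulated
exchangeable participants.

Because 500 permutations × every participant × (quadratic + power fit)
is expensive one model at a time, the permutation engine evaluates all
shuffles of a participant at once: the quadratic coefficients of all
permuted series come from one 3×n projector–matrix product, and the
log–log R² for every cut-off value from cumulative-sum algebra. The
engine is closed-form identical to the public single-series path, and a
test asserts equality to 1e-8 on both statistic definitions.

Univariate outliers in each tract metric are removed with the
median-absolute-deviation rule: values beyond 2.5 scaled MADs
(consistency constant 1.4826) from the median are dropped, per metric
rather than listwise — so each correlation reports its own analysed n.

## The correlation suite

Directions are fixed by the physiology: higher mean diffusivity (MD)
predicts slower learning (positive association with `b` and with mean
latency), higher fractional anisotropy (FA) predicts faster learning
(negative association). Accordingly:

* **Frequentist tests** are one-sided: Pearson `r` with
  `t = r√((n−2)/(1−r²))` on `n−2` df; Spearman's ρ as the Pearson
  correlation of mid-ranks with the same t approximation (adequate at
  the n ≈ 25–100 this design produces; ranks make it robust to
  univariate outliers).
* **Default Bayes factors** use the exact reduced likelihood of the
  population correlation ρ given `(r, n)` — the bivariate-normal
  likelihood with location and scale nuisance parameters marginalised
  under Jeffreys priors — integrated against a stretched-beta prior of
  width κ on (−1, 1). κ = 1 (uniform), the convention of the standard
  software defaults, is the package default. One-sided factors `BF₊₀` /
  `BF₋₀` truncate and renormalise the prior; for the symmetric prior
  `BF₁₀ = (BF₊₀ + BF₋₀)/2`, an identity the tests check by independent
  quadratures rather than by construction. The hypergeometric series in
  the likelihood is accumulated with a streaming log-sum-exp so the
  computation is stable at large n, and the two half-line integrals use
  a scale-aware absolute tolerance because the non-predicted side can
  carry ~20 orders of magnitude less mass than the predicted one.
* **Credible intervals** are central 95% intervals of the normalised
  posterior, obtained by quadrature of the CDF and root-finding on its
  quantiles; a posterior whose integral differs from 1 by more than
  1e-6 is rejected. The default interval uses the two-sided posterior;
  `side = "positive"/"negative"` gives the truncated-posterior interval
  that one-sided software reports alongside `BF₊₀`/`BF₋₀`.
* **Dependent overlapping correlations** (tract of interest vs
  comparison tract, sharing the behavioural variable) are compared with
  Steiger's (1980) Z using the pooled correlation
  `r̄ = (r_jk + r_jh)/2` in the asymptotic covariance, and — following
  robust practice — by a percentile bootstrap (default 1,000 resamples
  of complete participant triples) of the difference of Spearman
  correlations.
* **Partial correlations** residualise both variables on the covariates
  (with intercept) and correlate the residuals, with t on `n−2−k` df;
  the Bayesian counterpart is a Zellner–Siow mixture-of-g Bayes factor
  comparing the regression of the behavioural measure on
  {covariates, metric} against {covariates}. Directional JZS factors
  multiply the two-sided factor by twice the posterior sign
  probability, approximated by the classical t posterior — a
  default-prior construction whose second decimal can differ from other
  JZS implementations. Covariates in the pipeline are proportional
  hippocampal volume (volume / eTIV) and, separately, a 0/1 gender
  code.
* **Multiplicity** uses Bonferroni over the comparisons per metric
  class (default 2, so α = .05/2 = .025), echoed in the report.

All quadratures target absolute tolerance at or below 1e-8.

## The synthetic cohort generator

The generator's role is to give every pipeline stage a testable input
with known truth, with the statistical structure the analysis assumes:

* **Latency series.** `T(x) = min(t_max, a·min(x, plateau)^b·exp(ε))`
  with `ε ~ N(0, noise_sd²)` up to the plateau and
  `N(0, late_noise_sd²)` after it — a power law with lognormal trial
  noise, an early plateau, and variable late behaviour. Per-participant
  truth: `b ~ N(−0.32, 0.08)` truncated negative, `a ~ U(35, 60)` s,
  plateau uniform on trials 7–20. A configurable fraction (default
  0.15) of participants are planted non-learners with trend-free
  i.i.d. lognormal latencies, exercising the exclusion stage.
* **Noise scales.** The two free noise parameters were fixed once by a
  design analysis against the descriptive anchors this literature
  reports for successful learners: a fitted-b spread of about .08
  (range ≈ −.49 to −.19) and a mean cut-off near 14 of 20 trials.
  `noise_sd = 0.06`, `late_noise_sd = 0.45` reproduce those anchors
  (mean cut-off ≈ 14.8; fitted-b SD ≈ .093) while keeping the
  estimation chain close to unbiased (mean fitted − true b ≈ +0.003 at
  n = 1,000). Larger late-trial noise would sharpen the trough but
  contaminate the power fit whenever the estimated cut-off overruns the
  plateau; a systematic post-plateau slowing term was evaluated and
  rejected for the same reason.
* **Attenuation, by design.** Fitted `b` = true `b` + estimation noise,
  so cohort-level correlations computed against *fitted* `b` are
  attenuated by the reliability ratio SD(true)/SD(fitted) ≈ 0.85 at the
  default noise (more at small n). Tests that score the generator's
  correlation targeting therefore use the stored true `b`; tests of the
  full pipeline assert sign and ordering, not the unattenuated
  magnitude.
* **Tract metrics.** Fornix MD mixes the standardised true `b` (weight
  `target_r_fornix_md`, default .44) with independent Gaussian noise,
  so the population correlation equals the target by construction; ILF
  MD honours `target_r_ilf_md` (default 0), and volumes and gender are
  independent of `b`. FA is coupled to MD within each tract at −0.5 —
  the anatomically expected anticorrelation — which propagates a
  negative FA–behaviour association (≈ −.22 at defaults) without a
  separate dial. Scales are realistic for free-water-corrected adult
  data (MD ≈ 0.80 ± 0.05 ×10⁻³ mm²/s, FA ≈ 0.45 ± 0.04, bilateral
  hippocampus ≈ 7,800 ± 600 mm³, eTIV ≈ 1.5 ± 0.12 ×10⁶ mm³,
  volume–eTIV correlation 0.4).
* **Arena agent.** A step-walker (0.25 m per 0.1 s) in an 8 × 8 m
  square arena whose heading is, with probability `goal_bias`, the
  direct bearing to a hidden 0.8 × 0.8 m sensor square and otherwise
  uniform; walls reflect, trials end on sensor entry or at 60 s, and
  `goal_bias` can grow per trial to emulate learning. Start positions
  cycle through the four mid-wall cardinal starts within each block of
  four trials. The stated sensor size is kept as a parameter: a 0.8 m
  square is 1% of an 8 m arena's floor, not the 0.25% sometimes quoted
  alongside it, and the package does not adjudicate that inconsistency.
* **Reproducibility.** Every participant consumes an independent
  L'Ecuyer-CMRG substream of the master seed
  (`parallel::nextRNGStream`), so a cohort is byte-identical under the
  same seed and — because stream i depends only on (seed, i) —
  enlarging a cohort never changes earlier participants. All public
  functions restore the caller's RNG state, including the generator
  kind.

What the generator deliberately does not emulate: self-motion cues,
spatial strategies, trajectory structure beyond the toy agent,
inter-trial carry-over, or measurement error in the MRI-derived
metrics. Passing recovery tests therefore demonstrates that the
estimation chain is correct under the stated generative assumptions,
not that those assumptions exhaust real behaviour.

## Pipeline bookkeeping

`run_full_analysis()` applies the stages in order (fit → behavioural
screen → per-metric MAD screen → correlations → comparisons →
partials), and every reported n equals the count of participants
surviving the screens relevant to that specific analysis — the
per-metric MAD rule makes neighbouring correlations differ in n, which
is intended. Mean-latency analyses can optionally re-admit
behaviourally excluded participants (`include_excluded_in_mean_latency`,
default off). Reports serialise to JSON at full precision plus a cohort
CSV, and `write_report()` validates stage completeness before writing.

## Problem sizes in the shipped tests

The test suite exercises recovery at the scales the claims need: exact
identifiability on noiseless cohorts; parameter recovery at n = 1,000
(mean fitted b within ±.01, SD within ±.02 of truth); correlation
targeting at n = 10,000 (within ±.03 of .44); screen calibration with
2,000 exchangeable participants × 500 permutations (84% ± 3 points);
type-I calibration of the one-sided Pearson test over 10,000 null
replicates (5% ± 0.7); and 100-configuration formula oracles for
Steiger Z and partial correlations at 1e-10. The full suite runs in
about a minute on one CPU.

## Known limitations

* The cut-off trims, but cannot model, post-plateau behaviour; `b` is
  conditional on the estimated cut-off, and its estimation noise
  attenuates downstream correlations (see above).
* Spearman p-values use the t approximation, not the exact permutation
  distribution; an exact option would matter only below n ≈ 15.
* The JZS sign adjustment is an approximation to the truncated-prior
  one-sided Bayes factor.
* The permutation screen tests exchangeability against a monotone-fit
  alternative; participants who learn in a strongly non-power-law way
  (e.g. abrupt one-trial acquisition) are retained only insofar as a
  power curve fits them better than their shuffles.
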