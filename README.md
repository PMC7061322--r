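# navlearn

Individual-differences analysis of spatial learning in virtual Morris
Water Maze (MWM) tasks, for researchers relating navigational behaviour
to brain measures such as white-matter tract microstructure.

In a desktop MWM, a participant searches a square arena for a hidden
floor sensor over repeated trials (here: 20 trials, 60 s ceiling), and
the time to reach the sensor falls as the environment is learned. The
package turns each participant's latency series into a single
learning-rate index and carries that index through a screened,
directional brain–behaviour correlation analysis:

1. **Learning rate.** Latencies are modelled as a power law,
   `T(x) = a·x^b`, where `x` is the trial number and the exponent `b`
   (the slope on log–log axes) indexes learning rate — more negative is
   faster. Because fast learners often plateau early and then behave
   erratically, a second-order polynomial is first fitted to all trials
   and its trough (where the first derivative crosses zero) sets a
   per-participant cut-off; only trials up to the cut-off enter the
   power fit.
2. **Screening.** Participants whose fit is indistinguishable from
   chance are excluded by a permutation test: each participant's trials
   are shuffled 500 times, the fit statistic (R²) is recomputed per
   shuffle, and the participant is retained only if the true R² exceeds
   the 84th percentile of their own null (the upper edge of the central
   68% interval). Tract-metric outliers are removed per metric with a
   2.5-MAD rule.
3. **Inference.** One-sided Pearson and Spearman correlations in the
   predicted directions (mean diffusivity positive with `b`, fractional
   anisotropy negative), default Bayes factors `BF₊₀`/`BF₋₀` for
   correlations under a stretched-beta prior with 95% credible
   intervals, Steiger Z tests and a participant-level bootstrap for
   comparing dependent overlapping correlations (tract of interest vs a
   comparison tract), frequentist and JZS-Bayesian partial correlations
   (controlling proportional hippocampal volume, or gender), and a
   Bonferroni-corrected α (.05/2 = .025).

A synthetic cohort generator (latency series + correlated tract metrics
+ covariates + an arena navigation agent) makes the entire pipeline
testable without any data download, and ships the ground truth so
recovery can be scored.

## Worked example

Simulate a cohort with a planted fornix-MD/learning-rate correlation of
.44, and run the full pipeline:

```r
library(navlearn)

params <- cohort_params(n_participants = 120, seed = 11)
report <- run_full_analysis(analysis_config(params = params, seed = 11))
print(report)
#> Navigational-learning analysis report (seed 11)
#>   120 participants, 24 excluded by the behavioural screen
#>   Bonferroni-corrected alpha: 0.025
#>
#> Zero-order correlations (Pearson rows):
#>       measure    metric  n estimate        p       bf
#>             b fornix_md 95  0.22885 0.012850   2.9320
#>             b fornix_fa 91 -0.00306 0.488507   0.1341
#>             b    ilf_md 95 -0.18446 0.963234   0.0475
#>             b    ilf_fa 89  0.01038 0.538448   0.1230
#>  mean_latency fornix_md 95  0.36683 0.000128 185.1983
#>  ...
```

The planted effect appears where it should: fornix MD correlates
positively with `b` (r = .23, one-sided p = .013, BF₊₀ = 2.9 — the raw
correlation is attenuated relative to the .44 target because fitted
`b` carries estimation noise) and with mean latency, while both ILF
metrics stay at the null. `report$comparisons` confirms the
dissociation (fornix vs ILF MD: Steiger z = 2.61, p = .004; bootstrap
95% CI of the Spearman difference [.16, .75]), and `report$partials`
shows the fornix-MD association survives controlling hippocampal
volume (partial r = .23, BF₊₀ = 3.0) and gender. About 20% of
participants are excluded by the screen: the 15% planted non-learners
plus a few genuinely weak learners.

Per-participant pieces are exported individually:

```r
ch  <- simulate_cohort(params)
y   <- as.numeric(ch$latencies[1, -1])      # one learner's 20 latencies
derive_learning_rate(y)
#> Learning rate b = -0.321 (a = 53.2 s, R^2 = 0.935, trials 1..18)
#> Mean latency to cut-off: 28.80 s           # truth for this participant: b = -0.334

permutation_learning_null(y, n_perm = 500, seed = 1)
#> Permutation learning null (500 shuffles, full): true R^2 = 0.935,
#>   threshold = 0.145 -> retained

default_bf_correlation(0.44, 27, "greater")
#> Default correlation Bayes factor (r = 0.440, n = 27)
#>   BF+0 = 5.775 (prior width 1.00)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/navlearn.R` (`simulate`, `fit`, `screen`, `correlate`, `run`
subcommands; `--seed` is required for anything stochastic).

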