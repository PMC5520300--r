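# caceboot

Complier average causal effects for two-arm randomized trials with
all-or-nothing noncompliance, with BCa bootstrap uncertainty and power
calculations under compliance dilution.

## The problem

In a trial that randomizes an *offer* — here, financial voucher incentives to
pregnant smokers for biochemically validated cessation — the
intention-to-treat (ITT) comparison of a downstream outcome such as infant
birth weight dilutes any real effect, because only a minority of participants
change their behaviour because of the offer. Under monotonicity (no defiers)
and the exclusion restriction (randomization affects birth weight only
through quitting), the population divides into three principal strata:

* **hardened smokers** (never-quitters, proportion π_n): smoke in either arm;
* **independent quitters** (always-quitters, π_a): quit in either arm;
* **potential quitters** (compliers, π_c): quit only when offered incentives.

The stratum proportions are identified from the observed quit rates
(π_n from the incentives-arm continuing smokers, π_a from the control-arm
quitters, π_c = 1 − π_n − π_a), and the two observed "mixed" cells are
weighted means of stratum means, e.g. for the incentives-arm quitters

```
W_1 = (π_a · W_IQ + π_c · W_PQQ) / (π_a + π_c)
```

Solving the two mixture identities gives the unobservable complier means
with (`W_PQQ`) and without (`W_PQS`) the offer, and their difference is the
complier average causal effect (CACE). Algebraically the same estimator is
the instrumental-variable Wald ratio

```
CACE = (μ_1 − μ_0) / π_c
```

— the ITT outcome difference divided by the compliance gap. The package
computes both routes, verifies their identity, attaches 95% bias-corrected
and accelerated (BCa) bootstrap intervals to every stratum mean and to the
CACE, and sizes hypothetical future trials given that a complier-level
effect δ appears between arms only as π_c · δ.

## Worked example

Run the chain on the published summary table of the motivating trial
(582 analyzable mother/baby pairs):

```r
library(caceboot)
xt <- incentive_trial_table()
props <- strata_proportions(xt)
props
#> Stratum proportions: hardened smokers 0.769, independent quitters 0.087, potential quitters 0.143
means <- solve_potential_quitter_means(props, observed_means(xt))
means
#> Estimated stratum mean birth weights (g):
#>   hardened smokers                   3053.0
#>   potential quitters, no offer       3193.1
#>   potential quitters, offered        3338.5
#>   independent quitters               3586.0
cace_intuitive(means, props)
#> CACE (stratum-mean inversion): 145.4 g
```

Only 14.3% of women quit *because of* the offer, but for their babies the
estimated birth weight gain is about 145 g — seven times the 21 g ITT
difference, which on its own looks clinically negligible.

A full pipeline run on a synthetic cohort (with known latent strata and a
true 145 g complier effect) adds bootstrap intervals and the run log:

```r
cohort <- generate_cohort(reference_trial_config(seed = 3))
fit <- analyze(cohort, n_replicates = 2000, seed = 3)
fit$intervals
#> Bootstrap BCa intervals (2000/2000 valid replicates, within_arm scheme, seed 3)
#>   hardened smokers                 3099.2  [  3027.1,   3170.9]  95%
#>   potential quitters, no offer     2855.1  [  2434.7,   3236.9]  95%
#>   potential quitters, offered      3578.1  [  3384.5,   3762.2]  95%
#>   independent quitters             3462.6  [  3153.6,   3699.7]  95%
#>   complier effect (CACE)            723.0  [   309.0,   1197.7]  95%
```

At n ≈ 600 the CACE is estimated with an interval many hundreds of grams
wide (this seed happens to draw a cohort whose point estimate is far above
truth — exactly the sampling noise the interval is warning about). The
unoffered potential quitters are always the least-identified subgroup.

Designing a trial actually powered for the outcome shows why the original
one could not be:

```r
sample_size_two_sample_t(delta = itt_effect(100, 0.143), sd = 600)
#> [1] 27637
```

A clinically important 100 g complier effect, diluted to 14.3 g between
arms, needs 27,637 participants per group at 80% power.

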