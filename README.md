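# flocknbda

Network-based diffusion analysis (NBDA), order-of-acquisition variant
(OADA), for trait diffusions unfolding at **several food patches at once**
within social groups — the situation faced by captive house-sparrow flocks
offered two hidden food patches in the presence of two trained
("informed") flock-mates.

The package is for behavioural ecologists who have

* timestamped feeder-arrival logs from an independent observation period
  (to build directed weighted *following networks*: edge weight
  `a(i, j)` = rate at which bird *i* arrived within 5 s of initiator *j*,
  in followings/hour),
* per-flock, per-patch first-feeding latencies with right-censoring at a
  trial horizon, and
* bird-level covariates (sex, age, feeding activity),

and who want to estimate whether, and at which patch, the order of patch
discovery followed the social network.

## The model

Each naive bird *i* in flock *f* has first-feeding hazard at patch *p*

```
lambda_i(t) = lambda_0p(t) * exp(beta' x_i + u_f + v_i) * (1 + s_p * T_i(t)),
T_i(t)      = sum_j a_ij * w_j * z_j(t)
```

with patch-specific social-transmission parameters `s_p >= 0`,
demonstrator transmission weights `w_j` (visit counts scaled to the flock
maximum), informed status `z_j(t)`, and optional nested frailties
(individual in flock, Laplace-approximated). Fitting maximises the
stratified Cox-type partial likelihood over the combined diffusions
(baseline cancels; only the acquisition order matters). Model selection
crosses covariate subsets x five transmission scenarios x two network
types (measured vs homogeneous), ranked by AICc with Akaike weights,
category/network support percentages and a delta-AICc <= 4 best-models
set. Profile-likelihood CIs, likelihood-ratio tests against the asocial
model, Monte-Carlo stratified permutation tests (Wilcoxon-Pratt
signed-rank, Mann-Whitney, Spearman; resample-standardised Z, add-one
p-values) and the exact minimum-likelihood binomial test complete the
pipeline. A synthetic-flock generator with known parameters makes every
stage testable end to end.

## Worked example

```r
library(flocknbda)

## a synthetic study at the reference conditions: 10 flocks x 10 birds,
## two informed demonstrators per flock, s = (1.5, 0), beta_sexM = 0.4
dat <- simulate_flock_study(flock_scenario(n_flocks = 10, seed = 42))

fit <- fit_oada(oada_spec("following", "s_patch1_only", "sexM"),
                dat$diffusions, dat$networks, dat$roster)
fit
#> OADA fit: s_patch1_only, network=following, pooling=patch
#>   social transmission: s1 = 2.948
#>   covariates: sexM = 0.5278
#>   logLik -328.1557 on 90 events, k = 2, AICc 660.449

round(profile_ci(fit, "s1"), 3)
#> Warning: profile did not drop on the upper side
#> lower upper
#> 0.841   Inf

asoc <- fit_oada(oada_spec(scenario = "asocial", covariates = "sexM"),
                 dat$diffusions, dat$networks, dat$roster)
lrt_vs_asocial(fit, asoc)
#>  Likelihood ratio test of social transmission (vs asocial OADA)
#> X-squared = 32.182, df = 1, p-value = 1.404e-08
```

Reading the numbers: a bird's feeding hazard at patch 1 is multiplied by
`1 + 2.948 * T_i`, so one following-per-hour connection to a maximally
weighted informed bird (`T_i = 1`) roughly quadruples its discovery rate;
males discover patches `exp(0.53) ~ 1.7x` faster. On this replicate the
profile interval for `s1` is bounded away from 0 below but open above — a
common outcome in small diffusion studies whose acquisition order is
highly consistent with the network (the data cannot bound `s` from
above; the LRT against the asocial model is the sharper statement that
social transmission is present). The true generating values were
`s1 = 1.5`, `beta_sexM = 0.4`.

A full analysis (networks -> 72-model grid -> support -> statistics ->
tables and diffusion-curve figure) is one call:

```r
res <- run_pipeline(pipeline_config(
  scenario = flock_scenario(seed = 42), out_dir = "out", seed = 42))
res$support
```

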