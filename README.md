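# gompertzSM

Parametric survival analysis of rodent lifespan cohorts with the Gompertz
mortality model, built around one question that naive curve fitting gets
wrong: **when a cohort's lifespan changes, did the rate of aging change, or
the initial mortality?**

The Gompertz model writes the force of mortality at age *t* as

```
mu(t) = mu0 * exp(gamma * t)
```

with the initial mortality `mu0` (hazard extrapolated to age zero, an
inverse proxy for initial viability) and the rate of aging `gamma` (how fast
the hazard accelerates), giving the survivorship
`S(t) = exp(-(mu0/gamma) * (exp(gamma*t) - 1))`. The catch is the
Strehler-Mildvan correlation: the *estimation errors* of `ln mu0` and
`gamma` are negatively coupled, so refitting subsamples of a single
unchanged population scatters the estimates along a negatively sloped line
in the `(gamma, ln mu0)` plane. A treated-vs-control displacement that runs
along that line means little; only its deviation from the line carries
information. gompertzSM makes that reference line explicit and classifies
parameter-change vectors against it.

The package provides:

- **Closed-form Gompertz mathematics** — hazard, survivorship, quantiles,
  mean lifespan, seeded inverse-CDF sampling (`gompertz_*`,
  `sample_lifespans`).
- **Fitting** — censored maximum likelihood on per-animal lifespans
  (`fit_ml`) and Levenberg-Marquardt least squares on digitized
  survival-curve points (`fit_curve`), both with 95% confidence intervals,
  compared by interval overlap (`ci_overlap`). Published estimates enter
  via `fit_result`.
- **Artifact machinery** — artifactual reference regressions by subsample
  refitting (`build_reference_by_subsampling`) or from pooled control fits,
  change vectors (`change_vector`), and classification into
  `aging_rate_change`, `initial_mortality_change`, `mixed_real`,
  `largely_artifactual`, or `null` with a full continuous decomposition
  (`classify_vector`).
- **Nonparametric side** — cohort summaries, tumor-censored Kaplan-Meier
  curves with log-rank tests, Fisher/chi-square contingency tests, and
  windowed Mann-Whitney comparisons of organ panels.
- **Synthetic data** — seeded two-strain generators (lifespans with
  age-dependent postmortem tumor labels, curve tables with digitization
  jitter, serial-sacrifice organ panels) so the whole pipeline is testable
  without any raw-data download.

## Worked example

Two strains: a wild-type-like law (`mu0 = 1.4e-4`, `gamma = 0.0049`/day,
N0 = 69) and an accelerated-aging-like law (`mu0 = 1.3e-4`,
`gamma = 0.0077`/day, N0 = 46).

```r
library(gompertzSM)

scen    <- make_default_scenarios()
wt_coh  <- generate_cohort(scen$wt,  seed = 101)
k14_coh <- generate_cohort(scen$k14, seed = 102)

summarize_cohort(k14_coh)
#> Cohort summary 'K14-like' (N0 = 46)
#>   maximum lifespan: 702 days
#>   median lifespan:  501 days
#>   mean lifespan:    495 +/- 128 days
#>   last 5 survivors: 676 +/- 25 days

fit_wt  <- fit_ml(wt_coh)
fit_k14 <- fit_ml(k14_coh)
fit_k14
#> Gompertz fit (lifespan-ML, n = 46)
#>   mu0   = 5.41e-05 /day  (95% CI 1.73e-05 - 0.000169)
#>   gamma = 0.00931 /day  (95% CI 0.00709 - 0.0115)
#>   logLik = -285.985

ci_overlap(fit_wt, fit_k14, "gamma")   # "disjoint"    -> gamma differs
ci_overlap(fit_wt, fit_k14, "mu0")     # "overlapping" -> mu0 does not
```

The interval verdicts alone say "gamma changed"; the artifact check says how
much of the displacement refitting noise could explain:

```r
ref <- build_reference_by_subsampling(scen$wt$params,
                                      n_sub = 50, n_reps = 200, seed = 11)
ref
#> Strehler-Mildvan reference regression (subsampled-single-population)
#>   ln mu0 = -5.848 -617 * gamma   (r = -0.937, 200 points)

classify_vector(change_vector(fit_wt, fit_k14), ref)
#> SM classification: aging_rate_change
#>   orthogonal share 0.284, gamma share 0.964, mu0 share 0.036 (theta = 0.25)
```

The fitted change vector deviates from the artifact line (orthogonal share
0.28 ≥ θ = 0.25) and runs almost entirely along the gamma axis (share 0.96)
while the `mu0` intervals overlap: the lifespan deficit is attributed to a
genuinely faster rate of aging, not to lower initial viability. The
tumor-censored nonparametric comparison agrees:

```r
lr <- logrank_test(wt_coh, k14_coh, censor_rule = "tumor-bearing-only")
#> chisq = 53.0, p = 3.4e-13

fisher_exact(c(12, 34, 2, 67))$p.value   # papilloma prevalence contrast
#> 0.000277
```

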