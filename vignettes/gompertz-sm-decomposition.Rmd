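---
title: "Gompertz survival modelling and the Strehler-Mildvan artifact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gompertz survival modelling and the Strehler-Mildvan artifact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gompertzSM)
```

## The model

gompertzSM analyses rodent lifespan cohorts with the basic Gompertz mortality
model. The force of mortality (hazard) at age $t$ is

$$\mu(t) = \mu_0\, e^{\gamma t},$$

with two parameters, both rates per day: the *initial mortality* $\mu_0$, the
hazard extrapolated to age zero and an inverse proxy for initial viability,
and the *rate of aging* $\gamma$, the exponential slope of the hazard. The
survivorship implied by this hazard is

$$S(t) = \exp\!\left[-\frac{\mu_0}{\gamma}\left(e^{\gamma t} - 1\right)\right],$$

so $S(0) = 1$ exactly and $S \to 0$ as $t \to \infty$. Quantiles are closed
form, $t_p = \gamma^{-1}\ln\!\left[1 - (\gamma/\mu_0)\ln(1-p)\right]$, and
the mean lifespan has the closed form
$\gamma^{-1} e^{\mu_0/\gamma} E_1(\mu_0/\gamma)$ with $E_1$ the exponential
integral; the package computes the mean by adaptive quadrature up to the
$1-10^{-12}$ quantile plus a closed tail bound ($\int_T^\infty S \le
S(T)/\mu(T)$, valid because the hazard increases), and cross-checks against
the closed form in its tests.

The basic model deliberately omits an age-independent (Makeham) mortality
term and any frailty/heterogeneity structure: with cohorts of a few dozen
animals, the two-parameter law is what the data can support, and the
decomposition below is defined in its parameter plane.

## Fitting

Two estimation routes are provided, matching the two kinds of input that
occur in practice.

**Per-animal lifespans (`fit_ml`).** The censored log-likelihood

$$\ell(\mu_0,\gamma) = \sum_{\text{deaths}} \left[\ln\mu_0 + \gamma t_i\right]
  - \sum_{\text{all}} \frac{\mu_0}{\gamma}\left(e^{\gamma t_i}-1\right)$$

is maximized over $(\ln\mu_0, \gamma)$ — the log scale makes positivity of
$\mu_0$ structural and conditions the problem, since $\mu_0$ spans orders of
magnitude. $\gamma$ is box-constrained to $(10^{-6}, 1)$ per day. Because
the conditional MLE of $\mu_0$ at fixed $\gamma$ is closed form, the fit
first maximizes the one-dimensional profile likelihood over $\gamma$ and
then polishes the joint optimum with safeguarded Newton steps using the
analytic gradient and Hessian, stopping when the gradient norm falls below
$10^{-8}$ scaled by the number of deaths. This is deterministic, needs no
user-supplied starting value, and converges in a handful of iterations; the
profile search makes a separate binned-hazard initialization unnecessary
(that initialization is still used for the curve route below, where no
profile is available). Non-convergence raises an explicit error with
diagnostics rather than returning a doubtful optimum. Cohorts with fewer
than five observed deaths are refused.

95% confidence intervals are Wald intervals from the observed information
matrix, computed on the $(\ln\mu_0, \gamma)$ scale and back-transformed for
$\mu_0$. They are approximate at study sizes: across 500 simulated cohorts
of $n = 69$ the $\gamma$ interval covers the generating value in roughly
92–96% of replicates (checked in the test suite). A seeded nonparametric
bootstrap (percentile intervals) is available as an option. Small-sample
bias is real and documented rather than corrected: at $n = 46$, $\hat\gamma$
runs about +3% high and $\ln\hat\mu_0$ about 0.10 low on average, the two
errors being negatively coupled — which is exactly the phenomenon the
artifact machinery below exists to handle.

**Survival-curve points (`fit_curve`).** Published survival data usually
survive only as digitized curve points. `fit_curve` fits
$N_0 S(t)$ to (age, survivors) points by Levenberg-Marquardt least squares
on the same transformed scale, with intervals from the linearized covariance
at the optimum. Weighting is unweighted by default; binomial
inverse-variance weights ($N_0/[N(t)(N_0-N(t))]$) are an option, since the
variance of a survivor count is largest mid-curve. Degenerate inputs (flat
or single-step curves, or curves not spanning a two-fold drop) are refused.
Tied lifespans are handled exactly in both routes; nothing is jittered.

Fits are compared by 95%-CI overlap (`ci_overlap`): parameters are called
significantly different only when the intervals are disjoint.

## The Strehler-Mildvan artifact and vector classification

Across populations, $\ln\mu_0$ and $\gamma$ correlate negatively (the
Strehler-Mildvan correlation). Part of that correlation is real biology;
part is pure estimation artifact: the estimation errors of the two
parameters are negatively coupled, so refitting subsamples of a *single*
homogeneous population scatters the estimates along a negatively sloped line
in the $(\gamma, \ln\mu_0)$ plane even though the law never changed.
Attributing a lifespan difference to "faster aging" or "lower initial
viability" is therefore only safe if the observed displacement differs from
what that artifactual regression predicts.

`build_reference_by_subsampling` constructs the artifact explicitly: it
draws replicate cohorts from one law, refits each, and regresses
$\ln\hat\mu_0$ on $\hat\gamma$ by OLS ($\gamma$ as abscissa, matching the
conventional plot; total least squares was considered and rejected as the
default because the reference is defined by that published construction —
the point cloud is returned, so users can fit any line they prefer).
Defaults of 50 animals per subsample and 200 replicates give a stable line
in about a quarter second; the correlation is typically $r < -0.9$.
`build_reference_from_fits` does the same OLS across user-supplied control
fits, and `sm_reference` accepts a published line directly.

`change_vector` forms the displacement $v = (\Delta\gamma, \Delta\ln\mu_0)$
between a control fit and a treated fit, carrying the CI-overlap verdicts of
both components. `classify_vector` then works in a *normalized* plane in
which one reference-cloud standard deviation of $\hat\gamma$ and of
$\ln\hat\mu_0$ each map to unit length — raw units would make "orthogonal"
meaningless across scales. The vector is decomposed exactly into a component
along the unit reference direction and an orthogonal residual, and shares
are squared-norm fractions. The label rules, in order:

1. **null** — both CI flags overlap and both raw components are inside the
   null tolerance (default: the mean CI half-widths of the two fits).
2. **largely_artifactual** — the orthogonal share is below $\theta$
   (default 0.25): refitting noise alone walks this far along the line.
3. **aging_rate_change** — the $\gamma$ axis carries at least $1-\theta$ of
   the normalized vector and the $\mu_0$ intervals overlap.
4. **initial_mortality_change** — the symmetric case.
5. **mixed_real** — anything else.

Step 3 deliberately tests the axis share of the *full* normalized vector
rather than of the orthogonal residual. For a genuine aging-rate change the
residual itself splits between both axes (the orthogonal direction is
oblique), so a residual-share rule would label the textbook case "mixed";
once step 2 has established that the displacement is *not* mostly
reference-parallel, the question "which axis carries it?" is about the
vector, and the CI flag on the other parameter guards against hidden real
changes. $\theta$ has no published value — the source analyses speak only of
vectors "almost parallel to" or "clearly deviating from" the artifactual
slope — so it is exposed as a parameter, and the continuous decomposition is
always reported next to the label so any other criterion can be applied.
A subsampled single-population reference with non-negative slope violates
the defining artifact and is refused outright.

Under the default settings, the two-strain headline case (aging rate +57%
at unchanged initial mortality, study-sized cohorts) classifies as
`aging_rate_change` in the large majority of simulation replicates, while
pairs of subsamples from one law classify as `largely_artifactual` or
`null` in well over 90% — both properties are exercised in the test suite.

## Nonparametric side: summaries, Kaplan-Meier, tests

`summarize_cohort` reports maximum, median, mean ± sample SD, and the mean ±
SD of the "last 10% survivors", defined as the $\lceil 0.1 N_0\rceil$
longest-lived animals (7 of 69, 5 of 46); the cut is configurable because no
standard definition exists. Medians of even-sized cohorts are the mean of
the central order statistics. `percent_difference` rounds half away from
zero — the convention that reproduces printed difference columns of the form
−22.5%, −29%.

`km_estimate` wraps the product-limit estimator with cause-specific
censoring rules: under `tumor-bearing-only`, deaths without a postmortem
tumor become censorings at their death age, so the curve estimates the
probability of *not having died tumor-bearing* by an age; the
papilloma-excluding rule additionally censors deaths whose only finding is a
papilloma. `logrank_test` compares two cohorts under any of these rules.
Fisher's exact test (default at papilloma-scale counts), chi-square with or
without continuity correction, and windowed Mann-Whitney comparisons of
organ-panel variables round out the statistics; all four delegate to the
standard implementations and the Fisher route is verified against a full
hypergeometric enumeration in the tests.

## The synthetic-data generators

No raw per-animal data are published for studies of this kind, so the
package ships generators that emulate the study *structure* end to end:

- **Cohorts**: seeded inverse-CDF Gompertz lifespans; each death is labelled
  tumor-bearing with a logistic-in-age probability, then given a primary
  tumor type from a multinomial (with an optional secondary-label rule —
  in the accelerated strain, squamous-cell carcinomas ride along with
  papillomas, reflecting papilloma-to-carcinoma progression and making the
  papilloma weight 12/19 of tumor-bearing animals).
- **Curves**: the cohort's empirical step function, optionally with
  Gaussian age jitter emulating figure digitization (re-sorted to stay a
  valid curve).
- **Organ panels**: serial-sacrifice tables with exponential thymus
  involution and linear log2-thymulin decline (both roughly twice as fast
  in the accelerated strain, parameterized to nearly coincide at the first
  sacrifice age of 3 months so that group differences emerge only at later
  ages), logistic body-weight growth and constant spleen weight shared by
  both strains. The accelerated strain contributes nothing past 18 months —
  it does not live that long.

The default scenario pair carries the published point estimates
($\mu_0 = 1.4\times10^{-4}$, $\gamma = 0.0049$, $N_0 = 69$ versus
$\mu_0 = 1.3\times10^{-4}$, $\gamma = 0.0077$, $N_0 = 46$) and tumor-type
weights proportional to the published spectra. Everything else — logistic
tumor-age midpoints (800 and 520 days, scales 250 and 200 days) and all
organ coefficients — is fixture metadata chosen once to be qualitatively
realistic, *not* measurements; no quantitative acceptance check depends on
them.

What the generators do **not** emulate, and what passing tests therefore do
not show about real data: tumors are postmortem annotations, not competing
risks (they never shorten a lifespan); there is no cohort heterogeneity,
cage effect, or age-independent mortality; organ noise is Gaussian and
independent across animals; digitization error is age-axis-only jitter. The
generators validate the *machinery*, not any biological claim.

Every generator is a pure function of (scenario, seed); streams are scoped
with `withr::with_seed` (Mersenne-Twister, inversion normals), so no call
touches global RNG state and all results are bit-reproducible across
platforms.

## Numerical choices and problem sizes

- Quantile and sampling arithmetic uses `log1p`/`expm1` to avoid
  cancellation at extreme probabilities.
- Quadrature for the mean: relative tolerance $10^{-8}$, upper limit the
  $1-10^{-12}$ quantile plus the closed tail bound — no arbitrary "large
  number" truncation.
- Wald bounds for $\gamma$ are floored at $10^{-12}$ (positivity of
  reported bounds is enforced; at study sizes the floor is never active).
- The test suite runs its stochastic properties at deliberately desk-sized
  designs — 100–500 replicate fits, subsample references of 200 × 50, a
  3 × 3 parameter grid — chosen so the whole suite completes in well under a
  minute while keeping Monte-Carlo error small relative to the asserted
  margins; the acceptance script's 400 replicate fits run in about half a
  second.

## Limitations

- Maximum-likelihood Gompertz estimates at $n \lesssim 50$ carry a few
  percent of coupled bias ($\hat\gamma$ high, $\ln\hat\mu_0$ low); the
  package documents it and the artifact machinery is the intended remedy
  when *comparing* cohorts, but absolute parameter values from small
  cohorts should be read with that bias in mind.
- Wald intervals are approximate; the bootstrap option is slower but more
  honest for very small or heavily censored cohorts.
- The classification thresholds ($\theta$, the null tolerance) are
  explicit conventions, not estimated quantities; the continuous
  decomposition is the primary output and the label a summary of it.
- The curve-fitting route inherits whatever biases figure digitization
  introduced; its intervals describe least-squares uncertainty around the
  supplied points, not the original experiment.
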