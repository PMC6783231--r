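---
title: "Comparing count models for symptom-count surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing count models for symptom-count surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zicount)
```

## The problem

Symptom inventories in epidemiological surveys produce a count per
respondent: how many of the listed symptoms (here, the ten lower urinary
tract symptoms — LUTS — of the standard female questionnaire) she reports,
or how many of them she rates as bothersome. Such counts are non-negative
integers with two stubborn features. First, *overdispersion*: the variance
exceeds the mean, violating the Poisson equality assumption. Second, *excess
zeros*: around half the respondents report no symptom at all, more zeros than
a Poisson or even a negative binomial (NB) process with the observed mean
would produce. Modelling the count — rather than dichotomizing into
"any symptom yes/no" — keeps the severity information, but only if the
distributional family is chosen to match these features.

zicount implements the standard workflow for that choice and the analysis
that follows it: fit four candidate families by maximum likelihood, test for
overdispersion and excess zeros, select by log-likelihood/AIC/BIC, and report
the selected model's coefficients in the two-part convention.

## The four families

With covariate row vectors \(B_i\) (count section) and \(G_i\) (logit
section), the mean and structural-zero probability use log and logit links:

\[
\ln \mu_i = B_i\beta, \qquad
\operatorname{logit} \pi_i = \ln\frac{\pi_i}{1-\pi_i} = G_i\gamma .
\]

* **Poisson**: \(Y_i \sim \mathrm{Pois}(\mu_i)\); variance \(= \mu_i\).
* **NB**: \(Y_i \sim \mathrm{NB}(\mu_i, k)\) with dispersion \(k > 0\) and
  variance \(\mu_i + \mu_i^2/k\) (the "size" convention; smaller \(k\) means
  more conditional overdispersion).
* **ZIP / ZINB**: two-part mixtures. With probability \(\pi_i\) the
  respondent is a *structural zero* (not at risk of reporting symptoms);
  otherwise her count is Poisson or NB:

\[
P(Y_i = 0) = \pi_i + (1-\pi_i)f(0;\mu_i),\qquad
P(Y_i = y) = (1-\pi_i)f(y;\mu_i),\; y \ge 1 .
\]

The logit section answers *whether* a respondent has symptoms at all; the
count section answers *how many*, i.e. severity. A covariate may act on one
section, the other, or both, which is why the two sections may carry
different covariate sets (`design_spec(count_terms =, zero_terms =)`).

## Diagnostics and selection

**Overdispersion (O test).** From the sample size, mean and unbiased
variance,
\(O = \sqrt{n/2}\,(s^2/\bar x - 1)\),
approximately standard normal under Poisson equidispersion. Values at or
above 1.96 rule out the Poisson and ZIP families. `o_statistic()` takes the
three summary numbers; `o_test()` takes the outcome vector. Note 1.96 is the
two-sided 5% critical value, so the one-sided flag at 1.96 operates at the
2.5% level; this mirrors the convention of the survey literature the package
follows rather than a strict one-sided 5% test.

**Excess zeros (Vuong test).** For two non-nested fitted models with per-row
densities \(f_1, f_2\), \(m_i = \ln f_1(y_i) - \ln f_2(y_i)\) and
\(V = \sqrt{n}\,\bar m / S_m\). The workflow runs ZINB (model 1) against NB
(model 2): \(V \ge 1.96\) says the structural-zero component is needed. The
statistic is exactly antisymmetric in its arguments, and degenerates (no
information) when the two fitted densities coincide row by row; the
uncorrected form is used, without AIC/BIC penalty terms.

**Information criteria.** \( \mathrm{AIC} = -2\ln L + 2a\) and
\(\mathrm{BIC} = -2\ln L + a\ln n\) with \(a\) free parameters. BIC
penalizes harder than AIC once \(n > e^2\). `compare_models()` selects a
family only when the largest log-likelihood, smallest AIC and smallest BIC
agree; disagreement is reported as such (`agreement = FALSE`, `selected =
NA`) and never silently resolved, because the three criteria answer slightly
different questions.

## Fitting: numerical choices

Estimation is quasi-Newton (BFGS) on the unconstrained parameter vector
\((\beta, \gamma, \log k)\) with the analytic score, followed by Newton
polishing steps (Hessian from central differences of the score, step
\(10^{-5}\max(1,|\theta_j|)\)) until the score max-norm is below `grad_tol`
(default `1e-5`); hitting the 500-iteration cap sets `converged = FALSE`
instead of raising. Standard errors are the observed information — the
inverse negative Hessian at the optimum; 95% intervals are Wald
(estimate ± 1.96 SE), exponentiated for the logit section (odds ratios). No
profile-likelihood intervals and no multiple-testing adjustment are applied:
tables mirror the reporting convention of the survey literature, where each
covariate's interval is presented unadjusted. Treat p-values across a
12-covariate table accordingly.

Starting values matter for mixtures: the count section starts from a Poisson
fit, the zero-section intercept from the logit of the empirical excess-zero
fraction relative to that Poisson fit, and \(k\) from method-of-moments.
Degenerate inputs fail loudly and early: constant or collinear design
columns are named in the error; an all-zero outcome with a ZI family is
refused (\(\pi\) unidentified); \(\pi = 1\) is outside the parameter space.
The \(y = 0\) mixture mass is evaluated by log-sum-exp of
\(\{\ln\pi,\ \ln(1-\pi) + \ln f(0)\}\), the NB pmf through log-gamma
functions, and linear predictors are clamped at \(\pm 30\) inside the
optimizer so overflow can never surface as a silent `NaN`.

## The synthetic survey generator

No respondent-level data accompany the survey literature this workflow
targets, so the package ships a generator whose draws have the statistical
structure the analysis assumes, making every downstream stage testable.
`sample_covariates()` draws categorical covariates from declared marginals;
`simulate_outcome()` layers a ZINB (or ZIP/NB/Poisson) outcome on top via the
same links the models use.

`luts_like_preset()` is the package's reference configuration: twelve
categorical risk factors (age band, BMI class, menopausal status, parity,
perineal laceration, prolonged labor, constipation, pelvic organ prolapse,
diabetes, hypertension, smoking, alcohol) with round, documented marginal
frequencies — plausible for an adult-female community survey, but *not*
estimates from any dataset. Count-section effects use magnitudes typical of
reported severity associations (constipation 0.309, prolapse 0.348 on the
log-mean scale); logit-section effects are modest and negative for risk
factors. The intercepts and dispersion were set once, by moment matching, so
that a simulated survey reproduces the headline structure of the motivating
literature: ~45% zeros, mean count ~1.2, variance/mean ~1.8, overdispersion
statistic O ~ 80. The published moments do not identify how dispersion
splits between the structural-zero share and the conditional NB tail; the
preset puts \(\bar\pi \approx 0.28\) with conditional \(k = 6\), a split
strong enough that the structural-zero component is identifiable at
\(n = 20{,}000\) — consistent with the decisive excess-zero diagnostics the
motivating surveys report. `bother_like_preset()` is the heavier-zero
companion (~64% zeros, variance/mean ~2.8).

What the generator deliberately does **not** emulate: covariate
correlations (age and menopause are drawn independently; a joint
distribution is not published), multistage/stratified sampling and survey
weights, item-level missingness, and the hard ceiling of a finite symptom
inventory (counts are untruncated by default; `truncate_at = 8` caps them if
wanted, but the fitted models are untruncated, so the default keeps
generator and likelihood consistent). Passing tests on this generator
therefore validate the estimator and the selection workflow under the
assumed data-generating process — they do not validate those modelling
assumptions against real respondents.

## Validation design and problem sizes

The test suite validates each layer against an independent route:
log-likelihoods against brute-force per-row pmf summation, scores against
central finite differences, pmfs against direct normalization, fits against
closed forms (Poisson intercept-only), nested-family limits
(NB → Poisson as \(k \to \infty\), ZI → base as \(\pi \to 0\)), and full NB /
ZINB fits (coefficients, log-likelihood and standard errors) against
`MASS::glm.nb` and `glmmTMB`. Simulation studies run at the survey's own
scale where the property demands it: the decision-chain reproduction
(O ≥ 1.96, V ≥ 1.96, ZINB best by all three criteria) over 20 replicates of
\(n = 20{,}000\); parameter recovery — per-coefficient systematic bias below
0.05 and pooled 95%-interval coverage at least 90% — over 50 replicates of
\(n = 20{,}000\); O-test null calibration and AIC family recovery over 500
Poisson-truth replicates of \(n = 2{,}000\).

## Limitations

* Wald inference can undercover for rare covariate levels in small surveys;
  the observed-information SEs are exact asymptotically but nothing here
  protects a 2%-marginal dummy at \(n\) in the hundreds.
* The Vuong statistic is the uncorrected form; with many extra parameters in
  the larger model it is known to favour complexity slightly.
* Model selection is global: the same family serves both sections for every
  covariate. Per-covariate section choice is a modelling decision left to
  the analyst via `count_terms` / `zero_terms`.
* Associations from cross-sectional survey data, however well modelled, are
  not causal effects.
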