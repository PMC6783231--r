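# zicount

Count-model comparison and zero-inflated regression for symptom-count
surveys.

## The problem

Epidemiological symptom inventories — the motivating case is the count of
lower urinary tract symptoms (LUTS) reported by adult women on the standard
ten-item questionnaire — yield a non-negative integer outcome per
respondent. These counts are typically **overdispersed** (variance above the
mean) and **zero-inflated** (roughly half of respondents report no symptom,
more zeros than a Poisson or negative binomial process would give). Analysing
the count instead of a yes/no dichotomy preserves severity information, but
the distributional family must be chosen to match the data, and a
zero-inflated model separates two clinically distinct questions: *whether* a
respondent has symptoms at all (logit section, reported as odds ratios) and
*how many* she has (count section, reported as betas on the log-mean scale).

zicount implements the full workflow:

* maximum-likelihood fits of **Poisson**, **NB**, **ZIP** and **ZINB**
  regressions, with log link on the mean `ln(mu_i) = B_i beta` and logit link
  on the structural-zero probability `logit(pi_i) = G_i gamma`, where the
  ZI families put `P(0) = pi + (1 - pi) f(0)` and
  `P(y) = (1 - pi) f(y)` for `y >= 1`;
* the **O overdispersion test** `O = sqrt(n/2) (s^2/xbar - 1)` with its 1.96
  decision threshold;
* the **Vuong test** `V = sqrt(n) m_bar / S_m`,
  `m_i = ln f1(y_i) - ln f2(y_i)`, run as ZINB vs NB to detect excess zeros;
* **AIC/BIC selection** (`AIC = -2 ln L + 2a`, `BIC = -2 ln L + a ln n`)
  that picks a family only when log-likelihood, AIC and BIC agree;
* two-part **coefficient tables** (odds ratios with 95% Wald CIs for the
  logit section, betas for the count section), broom-style `tidy()` /
  `glance()` / `augment()` methods and `autoplot()` diagnostics;
* a **synthetic survey generator** emulating the excess-zero, overdispersed
  structure of LUTS-like data (`luts_like_preset()`, `bother_like_preset()`),
  so the entire pipeline is testable without access to raw survey data.

## Worked example

Simulate a survey with the statistical structure of a large LUTS study
(~45% zeros, mean count ~1.2, variance/mean ~1.8) and run the comparison:

```r
library(zicount)

d <- simulate_survey(luts_like_preset(), n = 20000, seed = 1)
mean(d$y == 0)   # 0.4478
mean(d$y)        # 1.197
var(d$y)         # 2.202

des <- design_spec(luts_schema())
cmp <- compare_models(d, des)
cmp
#> <zicount_comparison> outcome: y  n = 20000
#>   family    loglik      AIC      BIC n_free_params converged
#>  poisson -31309.04 62652.08 62786.44            17      TRUE
#>       nb -29678.97 59393.94 59536.20            18      TRUE
#>      zip -29613.37 59294.74 59563.46            34      TRUE
#>     zinb -29475.55 59021.11 59297.73            35      TRUE
#>   O test: 83.940 (overdispersed)
#>   Vuong (ZINB vs NB): 10.576 (excess zeros)
#>   selected: ZINB - ZINB attains the largest log-likelihood and the
#>   smallest AIC and BIC
```

Reading it: `O = 83.9 >= 1.96` rules out the equidispersed families
(Poisson, ZIP); `V = 10.6 >= 1.96` says the NB cannot account for the zeros;
and ZINB attains the best value of all three fit statistics, so it is the
selected model. Its coefficients, in the two-part reporting convention:

```r
ct <- coefficient_table(cmp$fits$zinb)
ct[ct$variable %in% c("constipation", "pop") & ct$level == "yes", ]
#>  section     variable level estimate std_error ci_low ci_high transformed  p_value
#>    logit constipation   yes   -0.448    0.0759  0.550   0.741       0.639 3.42e-09
#>    logit          pop   yes   -0.331    0.1244  0.563   0.917       0.718 7.84e-03
#>    count constipation   yes    0.318    0.0212  0.277   0.360          NA 8.73e-51
#>    count          pop   yes    0.367    0.0347  0.299   0.435          NA 4.40e-26
```

Logit-section rows are odds ratios (`transformed`, CI on the OR scale):
constipation lowers the odds of being a structural zero (OR 0.64), i.e.
raises the odds of having any symptoms. Count-section rows are betas on the
log-mean scale: constipation multiplies the expected symptom count among
symptomatic respondents by `exp(0.318) ≈ 1.37`. Both recover the generator's
true effects (0.309 and 0.348) within their Wald intervals.

`autoplot(cmp)` draws the AIC/BIC comparison;
`autoplot(cmp$fits$zinb)` overlays expected on observed count frequencies.

An end-to-end run (simulate or load a CSV, analyse several outcomes, write
fit-statistics, OR/beta tables, diagnostics and a JSON report) is
`run_pipeline(pipeline_config(...))`; a thin command-line wrapper with
`simulate` / `analyze` / `compare` subcommands is in `inst/cli/zicount.R`.

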