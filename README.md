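# countyswing

County-level ecological analysis linking changes in age-adjusted death
rates to changes in US presidential voting, with a synthetic-data
generator so the whole pipeline runs and is testable at desk scale
without any external data.

## The problem and the model

Between the 2008 and 2016 presidential elections, the Republican vote
share rose in most US counties while mortality trends diverged sharply
between large urban and small rural counties. The analysis this package
implements asks whether a county's change in its age-adjusted death rate
between 2000 and 2015 was *independently* associated with its voting
swing, after controlling for demographic and socioeconomic change.

The outcome is the **net Republican percentage gain**,

```
g = (R2016 − R2008) + (D2008 − D2016)      [percentage points]
```

a signed sum: it is positive in counties where the Democratic share fell
by more than the Republican share did, and negative where both parties
lost ground to third-party candidates asymmetrically.

The core model is a linear mixed model over counties i nested in states
s:

```
g_is = x_is' β + u_s + (β_death + v_s) · Δrate_is + ε_is
(u_s, v_s) ~ bivariate normal, free covariance
```

where `x` holds the 2000→2015 changes in median age, % Black, %
Hispanic, % Asian/Pacific Islander, median household income ($1000s),
unemployment %, % bachelor's degree or higher, % insured, plus a rural
indicator and a piecewise log10(population) term with its knot at a
population of 50,000; `Δrate` is the change in the directly
age-standardized all-cause death rate (per 100,000, US 2000 standard
million). The state random slope `v_s` lets the death-rate association
differ by state, which drives the swing-state counterfactual: a state's
required death-rate reduction to offset a victory margin `m` is
`m / (β_death + v_s)`.

Around that core the package provides:

- **Direct age standardization** (`age_adjust`) and group rate contrasts
  (`rate_contrasts`) in the CDC WONDER 11-age-group convention.
- **Multilevel left-censored Bayesian imputation**
  (`fit_imputation_model`) for suppressed "deaths of despair" counts
  (counts 1–9 withheld by the provider): an interval-censored Poisson
  model with nested state/county random intercepts, fitted by MCMC
  (JAGS), yielding M completed datasets pooled with **Rubin's rules**
  (`rubin_combine`).
- **State-clustered group comparisons** (`compare_groups`,
  `election_interaction_model`) — random-intercept models that keep the
  type-I error honest where a naive two-sample test is badly
  anti-conservative.
- **Sensitivity analyses** (`sensitivity_suite`): population-weighted
  fit, principal-component covariates, and the 2000-election-baseline
  outcome.
- **A synthetic county generator** (`generate_panel`) reproducing the
  panel's statistical structure: ~3,100 counties in 50 states,
  heavy-right-skewed populations, state-clustered vote swings, Poisson
  death counts with realistic suppression, and known ("oracle") truth
  for every hidden quantity.

## Worked example

```r
library(countyswing)

sim   <- generate_panel(generator_config(seed = 42))
rates <- age_adjust(sim$deaths[sim$deaths$cause_group == "all_cause", ])
des   <- build_design(sim$panel, rates)
fit   <- fit_primary(des)
fit
#> Multivariable random-effects model (g, n = 3070)
#>            term estimate       se  p_value
#> 1   (Intercept) 32.33959 1.979362 5.26e-60
#> ...
#> 10       d_rate  0.00772 0.000806 9.43e-22
#> 11        rural  3.42369 0.438786 6.06e-15
#> 12       l10pop -2.70368 0.333335 5.02e-16
#> 13        hinge -4.57503 0.728267 3.34e-10
#>   state intercept var 56.306 | slope var 9.74e-06 | rho 0.70
#>   R2 fixed 0.220 | R2 fixed+random 0.632 (variance of predictions ...)
```

The fitted death-rate coefficient (`d_rate`, points of net gain per
1/100,000 of rate change) inverts to the table presentation — the
death-rate difference associated with one point of net gain:

```r
1 / fit$coefficients$estimate[fit$coefficients$term == "d_rate"]
#> [1] 129.45
```

and feeds the counterfactual:

```r
margins <- data.frame(state_id = fit$state_slopes$state_id[1:3],
                      victory_margin = c(0.22, 0.72, 0.76))
electoral_counterfactual(fit, margins)[, c("state_id", "slope_per_1pct",
                                           "required_reduction_reported")]
#>   state_id slope_per_1pct required_reduction_reported
#> 1      S01      236.11031                          52
#> 2      S02       91.78774                          66
#> 3      S03      175.50524                         133
```

(`required_reduction(80, 0.22)` with the published Michigan slope and
margin reports 18 per 100,000.) `run_pipeline(run_config(seed = 1))`
chains every stage — simulate, classify, standardize, impute, compare,
fit, counterfactual — and writes the table-shaped CSV bundle.

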