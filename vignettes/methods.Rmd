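---
title: "Methods: mortality change, vote swing, and censored-count imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mortality change, vote swing, and censored-count imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models it fits, the choices that were genuinely open and how they
were settled, what the synthetic-data generator does and does not
emulate, and the numerical conventions used throughout.

## 1. The outcome and county classifications

The outcome is the net Republican percentage gain between two elections,
`g = (R16 − R08) + (D08 − D16)`, in percentage points. Two things about
this statistic are easy to get wrong:

* It is a **signed** sum. Truncating the two party movements at zero
  would make `g` non-negative, but negative county gains are an observed
  and meaningful part of the distribution (third-party surges depress
  both major parties). `net_republican_gain()` therefore never
  truncates.
* Its symmetry is subtle: swapping the two parties flips the sign, and
  reversing the order of the elections flips the sign, but doing *both*
  restores the original value (each movement is negated twice). The test
  suite asserts exactly this.

Counties are classified by the joint direction of the two party-share
changes (`republican_gain`, `democratic_gain`, `both_decline`,
`both_gain`). Exact ties count as "no gain" for that party; a
double-tied county falls into `both_decline` with a warning — the
source data conventions are silent here, so the package picks the
conservative bucket and says so out loud. Marginal, table-style counts
double-count a `both_gain` county in both parties' totals, which is why
published marginals can sum to one more than the number of counties.

## 2. Direct age standardization

`age_adjust()` computes `100000 × Σ_a w_a (count_a / py_a)` per county,
period and cause group. The standard population defaults to the US 2000
standard million in the 11-age-group convention used by CDC WONDER
(`us_standard_population()`; a CSV copy ships in `inst/extdata/` and
`read_standard_population()` accepts alternatives). The exact standard
an analysis used is often unstated in publications; this default is the
convention of the mortality source the analysis assumes, and it is
configurable precisely because it is an assumption.

Degenerate strata: a stratum with zero person-years and zero deaths
contributes zero with a warning; zero person-years with nonzero deaths
is an error, not a silent infinity. Censored cells must be imputed
first — `age_adjust()` refuses `NA` counts.

## 3. Left-censored Bayesian imputation of suppressed counts

Mortality providers suppress small counts: cells with 1–9 deaths are
withheld (zeros are published). Statistically each suppressed cell is
interval-censored on `[1, 9]`. The imputation model
(`fit_imputation_model()`) is a multilevel Poisson regression:

```
count ~ Poisson(mu),  log(mu) = offset + b0 + b_period·[t = 2015]
                                + u_state + w_county
u_state ~ N(0, σ_u²),  w_county ~ N(0, σ_w²)
```

with weakly-informative normal priors on the fixed effects and
half-normal priors on the random-effect scales. Censored cells
contribute the Poisson mass over the interval; completed datasets draw
the latent counts from their posterior, which is automatically
restricted to the interval. Fitting is by MCMC in JAGS, with the model
written in the hierarchically centered parameterization (county effects
centered on their state mean, state means on the global intercept) —
the flat parameterization mixes an order of magnitude worse under
JAGS's samplers.

Design choices worth knowing:

* **The age dimension lives in the offset.** Cells are county × period
  × age group, and rare-cause mortality has a strong age profile.
  Rather than estimate 11 age effects inside the MCMC, the offset is
  `log(person_years × shape_age)` with a fixed relative age shape
  (working-age-concentrated for the despair stream). The minimal linear
  predictor (intercept + period + state + county) sits on top of that
  offset. For tables without the standard age groups the shape
  falls back to 1.
* **Imputed values are integer counts**, drawn from the truncated
  posterior of the latent count, not continuous rates — downstream age
  adjustment stays count-consistent, and the mean-of-datasets rate
  equals the rate of the mean dataset (adjustment is linear in counts;
  a test asserts the two pipelines agree to 1e-9).
* **M = 10** completed datasets by default, taken at evenly spaced
  draws across chains; M, priors, chain settings and the censoring
  interval are all config-exposed (`imputation_spec()`,
  `censoring_rule()`) because the reconstruction is necessarily
  underdetermined — the analysis this mirrors did not publish its exact
  prior and M choices.
* **Convergence is a hard gate.** The per-parameter diagnostic is the
  rank-normalized split-chain scale reduction (Vehtari et al., 2021);
  any parameter above `rhat_max` (default 1.05) is an error carrying
  the diagnostics, never silent output. Rank normalization matters
  here: the classic statistic over-reads on the heavy-tailed posterior
  of `σ_u` when there are only a handful of states, flagging chains
  that are demonstrably converging.

Calibration on synthetic data is assessed two ways
(`imputation_calibration()`): raw coverage of the central 90% posterior
interval, which for *discrete* posteriors is conservative by
construction (discrete quantiles cannot cut mass at exactly 5%, so
~96% raw coverage is the signature of a well-calibrated count model,
not a miscalibrated one), and the randomized-PIT coverage, the standard
discrete-data calibration measure, which should be — and is — within a
few points of 90%.

Estimates computed per completed dataset are pooled with Rubin's rules
(`rubin_combine()`): mean of estimates; total variance
`W̄ + (1 + 1/M)B`; small-sample degrees of freedom
`(M−1)(1 + W̄/((1+1/M)B))²`, with `df = Inf` when the imputations agree
exactly.

## 4. State-clustered comparisons

Group means of county characteristics are compared with
`value ~ group + (1 | state)` fitted by REML; the reported means and SDs
are the unweighted county summaries (table style) while the difference
and p-value are model-based. P-values use the large-sample normal
reference — with thousands of counties the distinction from a t
reference is negligible, and the package documents rather than hides
the choice.

Clustering is not a formality. Vote swing clusters strongly by state, so
group membership is state-correlated and the naive pooled two-sample
test is badly anti-conservative: in the package's null calibration
study (state SD equal to the residual SD, groups assigned at the state
level, the configuration that mirrors the real data) the naive test
rejects a true null roughly a third of the time at α = 0.05 while the
random-intercept test stays within a couple of points of 0.05. The
acceptance suite measures exactly this, at 1,000 replicates of a
40-state × 8-county panel.

The two-election widening question uses the concatenated panel and a
3-level random-intercept model, `value ~ group × election + (1 | state)
+ (1 | state:county)`; the interaction contrast estimates how much the
group gap moved between elections.

## 5. The multivariable random-slope model

`fit_primary()` fits, by **maximum likelihood** (not REML — so the R²
decomposition and nested comparisons are likelihood-coherent):

```
g ~ Δcovariates + Δrate + rural + log10(pop) + hinge
    + (1 + Δrate | state)
```

* **Piecewise population effect.** The basis is the hinge pair
  `{log10(pop), max(0, log10(pop) − log10(50000))}`, continuous at the
  knot by construction; `pop_slopes` re-expresses the fit as the
  below-knot and above-knot slopes per 10-fold population increase, the
  presentation used in published tables.
* **Rural** is classes 5–6 of the 6-level urban–rural scheme (the
  non-metro classes). The cut is configurable
  (`build_design(rural_classes=)`) because the source convention is not
  stated.
* **Units** follow the published table: income in $1000s, death rate
  per 1/100,000, everything else in its natural percentage/year units.
  Internally the death-rate change is divided by 100 before entering
  lme4 (variance components on a sane scale for the optimizer) and all
  reported quantities are back-transformed.
* **The reciprocal presentation.** Published tables report "the
  magnitude of covariate change associated with each 1% net gain",
  which is `1/coefficient`; `magnitude_per_1pct` carries it, and a test
  asserts `magnitude × coefficient = 1` programmatically.
* **R² convention.** Published R² values for mixed models are
  ambiguous; the package computes `var(predictions)/var(outcome)` with
  fixed-only predictions (`r2["fixed"]`) and fixed-plus-BLUP
  predictions (`r2["total"]`), and names the convention in its output
  (`r2_convention`). `0 ≤ R²_fixed ≤ R²_total ≤ 1` is asserted in the
  suite.
* **Singular fits** (random-effects covariance on the boundary) trigger
  a refit with independent intercept and slope plus a prominent
  warning — never a silent near-singular covariance.

Complete-case analysis mirrors the published handling: counties missing
any covariate are excluded before fitting, with the exclusion count
logged.

The three sensitivity analyses (`sensitivity_suite()`) are (1) weights =
county population; (2) the eight demographic/socioeconomic changes
replaced by principal components of their standardized values retaining
a configurable variance fraction (default 0.90 — the source analysis
does not state its retention rule, so it is exposed; retaining
everything reproduces the primary fitted values exactly, a rotation
invariance the suite asserts); (3) the outcome recomputed against the
2000 election baseline, which the generator supports by emitting 2000
vote shares. A secondary model (`fit_despair_split()`) splits the rate
change into despair and other-cause streams, fitted per imputed dataset
and Rubin-pooled; it uses a state random intercept only, because
per-stream random slopes are not identifiable at these panel sizes.

## 6. The counterfactual

`state_slope()` inverts a state's total fitted slope
(`β_death + v_s`, points per 1/100,000) into death-rate units per point
of net gain; `required_reduction()` multiplies by the victory margin and
reports the nearest integer per 100,000 (half-up; full precision is
retained in the same row). Near-zero total slopes are refused — the
reciprocal is unstable — and negative slopes are an error because the
counterfactual direction is undefined. Every output row is labeled
association-based, not causal.

## 7. What the synthetic generator emulates — and what it does not

`generate_panel()` produces ~3,100 counties in 50 states (per-state
county counts lognormal, minimum 3), populations 10^N(4.4, 0.65)
(median ≈ 25,000, heavy right tail), six urban–rural classes cut at
populations of 10k/50k/250k/1M/5M, and covariate baselines and
2000→2015 changes drawn at the means and spreads of the published
county tables (majority-group column). The generating coefficients
default to the reciprocals of the published magnitudes-per-1%-gain;
state intercepts have variance 61.87 and intercept–slope correlation
0.49 as published. Two generator parameters could not be taken from the
source and were fixed once on first-principles grounds:

* the state random-slope SD (0.003 points per 1/100,000, ≈40% of the
  fixed slope) — the published slope variance (0.70) is not on a scale
  consistent with the published fixed coefficient (1/131 ≈ 0.0076), so
  it was evidently reported on a rescaled covariate;
* the residual SD (6.8 points), back-solved from the published R²
  decomposition (total 0.68 at an outcome SD of roughly 13).

Death counts are Poisson by county × period × cause × age with
person-years from a mildly perturbed standard age structure; the
all-cause cell count is the sum of the despair and other-cause draws,
so the cause hierarchy holds cell-by-cell. The net gain is assembled
from the *realized* (count-derived) rate change, so the fitting model
is exactly correct and parameter-recovery tests are clean
identification checks, not errors-in-variables studies. Vote shares
follow from `g` and a third-party dynamic (`ΔR − ΔD = g`,
`ΔR + ΔD = −Δother`), which makes both-parties-decline counties arise
naturally; shares pushed outside [0, 100] are clipped and counted.
True values of suppressed cells go to a separate oracle table that the
public outputs never contain.

Deliberately **not** emulated: geographic adjacency and real FIPS
codes, turnout dynamics, spatial correlation beyond state nesting,
covariate–covariate correlation structure (changes are drawn
independently), and any county-level relationship between covariate
changes and the death-rate change other than the population–mortality
gradient. Passing recovery tests on these panels therefore shows the
estimators are correct under the model's own assumptions — it cannot
show robustness to the confounding structures real county data may
hold.

Suppression realism has one subtlety the tests respect: zeros are
*published*, so the fraction of suppressed cells is monotone in county
population only among cells where deaths occurred; unconditionally,
tiny counties are mostly zeros and the fraction bends back down.

## 8. Problem sizes, seeds and numerical conventions

Reproducibility is absolute given a seed: one master seed expands into
per-stage seeds (`stage_seed`, a fixed affine fold into 32-bit range),
JAGS chains get derived RNG seeds, and regenerating or re-running any
stage is bit-identical — the suite asserts it.

The study-scale checks run at the analysis' own size (~3,100 counties /
50 states; 20 seeded replicates for coefficient recovery). The MCMC
calibration study uses 8-state × 8-county panels (≈1,400 despair cells,
a quarter of them censored) with 2 chains × 2,500 warmup + 1,500 kept
draws per fit, and the clustered-test calibration uses 1,000 null
replicates of a 40 × 8 panel — sizes chosen so each property is measured
with useful precision at interactive cost. Percentages print at one
decimal (half-up) where the mirrored tables print one decimal, integers
where they print integers; all computation keeps full precision and
rounding happens only at the reporting edge (`round_half_up`).

## 9. Known limitations

* The imputation model is a reconstruction: the original analysis'
  priors, covariates and M are unpublished, and eTable-level details
  (the exact cause-of-death code set) are taken as the field's
  convention (alcohol-related, drug poisoning, suicide) and exposed as
  configuration.
* County-level association is ecological; nothing here identifies
  individual-level behavior, and the counterfactuals are explicitly
  labeled non-causal.
* `σ_u` mixes slowly when a panel has very few states; the convergence
  gate will (correctly) refuse such fits rather than return them —
  lengthen the chains or enlarge the panel.
* The generator's independence assumptions above mean multicollinearity
  stress-testing of the PCA sensitivity is out of scope for the shipped
  panels.
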