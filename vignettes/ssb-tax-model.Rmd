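---
title: "Modelling the health impact of SSB taxation in Vietnam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health impact of SSB taxation in Vietnam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

`ssbtax` implements a multi-stage comparative risk assessment of excise
taxation on sugar-sweetened beverages (SSBs) for the Vietnamese adult
population. This vignette is the package's account of the model: the causal
chain and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## The causal chain

Each tax scenario is propagated through five stages:

1. **Tax → retail price.** The excise applies to the ex-factory price.
   Full (100%) pass-through to the factory price corresponds to roughly a
   50% pass-through of the tax amount to the retail price. The five shipped
   scenarios carry the average retail price increases produced by an
   external tax-incidence model (5%, 11%, 19%, 20%, 20%) as overrides;
   `retail_price_increase()` can also price volumetric and sugar-based
   specific taxes from a user-supplied category price table.
2. **Price → consumption.** A linear point-elasticity demand response,
   ΔV = ε·Δp·V with ε = −1.14, uniform across categories, population groups
   and time. The linear (rather than constant-elasticity power) form is
   deliberate: the modelled scenario set scales exactly linearly — the 20%
   price rise produces exactly four times the 5% response — and only the
   linear form preserves that ratio.
3. **Consumption → sugar → energy.** Volume changes are converted to sugar
   via the mean sugar density and to energy at 16.7 kJ per gram of sugar
   (4 kcal/g). Category densities are fixed constants (carbonates 11,
   juices 7, RTD tea/coffee 9, energy/sport 16 g/100 ml); low-calorie
   product lines are not modelled separately — category-average densities
   apply to total volumes.
4. **Energy → weight.** Equilibrium energy-balance coefficients by age band
   and sex (`energy_weight_params()`): adults 93.0 (men) and 72.3 (women)
   kJ·day⁻¹ per kg of steady-state weight change; ages 2–5 fixed 216/204
   kJ·day⁻¹ per kg; ages 6–17 the linear equations kcal·day⁻¹·kg⁻¹ =
   68 − 2.5·age (boys), 62 − 2.2·age (girls). Because roughly 95% of the
   equilibrium change is attained within three years, results are reported
   at the 3-year horizon as the full equilibrium change; a
   `maturity_fraction` parameter (default 1.0) lets users report the 0.95
   fraction instead. No within-horizon trajectory is modelled. The same
   per-capita energy decrease is applied to every adult — the model works
   on means, not on individual consumption heterogeneity.
5. **Weight → BMI → diabetes burden.** Sex-specific weight reductions are
   applied to each cohort member with heights held fixed, BMI is
   reclassified under the WPRO cut-offs (23/25/30), and prevalences are
   survey-weighted. The mean BMI reduction drives a relative risk reduction
   of type 2 diabetes of 27% per 2 kg/m² (95% CI 23–30%), applied to a
   baseline prevalence of 4.1% among 67 million adults aged 18–69; avoided
   cases are costed at a blended treatment cost and reported in VND and
   USD (22,370 VND/USD).

## Market calibration

The baseline market volumes come from a proprietary database, so
`calibrate_market()` inverts the published scenario impacts instead: the
10%-ad-valorem scenario (5% price rise, 171.3 million litres/year decrease,
2.6 litres/person/year, 0.8 g sugar/person/day) pins down the aggregate
baseline volume (171.3/0.057 ≈ 3,005 million litres/year), the implied
population (171.3 × 10⁶/2.6 ≈ 65.9 million) and the consumption-weighted
mean sugar density (≈ 11.2 g/100 ml).

Two consequences are worth stating plainly. First, the implied population
(65.9 M) is smaller than the census population aged 2+ (~93 M) that the
per-capita figures nominally reference; the package uses the calibrated
value by default because internal consistency of the published impact table
is what makes the chain reproducible, and it is configurable. Second, the
published totals for the volumetric scenarios (334.0 and 641.0 million
litres/year at 11% and 19–20% price rises) are *not* linear multiples of
the calibration scenario — they embed category-level price heterogeneity
that cannot be reproduced without the non-public per-category price table.
The single-aggregate linear model yields 376.9 and 650.9 for those
scenarios and exactly 4 × 171.3 = 685.2 for both 20% scenarios (published:
684.9). Downstream stages that need the published per-scenario inputs can
take them from `published_market_impacts()`.

## The synthetic cohort

`generate_adult_cohort()` stands in for the restricted national risk-factor
survey (3,856 adults aged 18–69 with survey weights). What it emulates is
exactly the statistical structure the downstream stages consume:

* **Weighted BMI class shares.** Per sex, class membership (below /
  overweight / obesity I / obesity II) is allocated by deterministic
  largest-remainder counts matching the targets (male 19.2/13.1/1.7%,
  female 16.5/14.2/5.1%; overall 17.9/13.6/3.4% at the default 50/50 sex
  split — the survey's actual split is unpublished).
* **Within-class BMI shape.** A base log-normal per sex is least-squares
  fitted to the three target tail probabilities and truncated to each class
  interval. A pure two-parameter log-normal cannot match all three class
  shares simultaneously (fitting any two leaves the third off by 1–3
  percentage points), which is why the generator is a class mixture rather
  than a single parametric draw.
* **Mean BMI.** The below-23 component keeps the fitted scale but its
  location is root-found so the per-sex mean BMI hits its target (male
  21.98, female 21.94 kg/m², reconstructed as the post-tax scenario-1 means
  plus the scenario-1 BMI reductions; the overall 21.96 is a soft target —
  the baseline mean is never published directly).
* **Auxiliary variables.** Heights are truncated normal (male mean 1.62 m,
  female 1.53 m, SD 0.06 — synthetic plausible values, not survey
  estimates; BMI is the calibrated quantity and weight = BMI·height²).
  Survey weights are i.i.d. gamma with mean 1 (shape 10), enough to
  exercise the weighted estimators without replicating the survey's
  unpublished cluster/stratum design. Ages are uniform on 18–69; no adult
  stage depends on age.

What it does **not** emulate: the complex survey design (so linearised
standard errors here are smaller than design-based ones), age–BMI
correlation, household structure, and any covariance between weights and
anthropometry. Passing calibration tests therefore show that the pipeline
is correct *given* a cohort with the published marginal structure — not
that the generator reproduces the real survey's joint distribution.

Infeasible targets (for instance a target mean no mixture over the class
intervals can reach) abort with diagnostics rather than silently degrading.

## Uncertainty analysis

Monte Carlo resampling is at parameter level, once per iteration, not per
person. Model 1 draws the two adult conversion factors from normal
distributions; model 2 additionally draws the diabetes RRR from a beta
distribution. All conversion-factor draws are taken before any RRR draws,
so models 1 and 2 share identical weight-change draws under the same seed —
which makes the variance ordering between models exact rather than
stochastic. Non-positive conversion-factor draws (the normal has unbounded
support) are rejected and redrawn, with the count logged.

* **Conversion-factor SDs** are not published. The default is a 5%
  coefficient of variation, calibrated so the simulated weight-change SDs
  match the magnitude of the published Monte Carlo SDs (e.g. ≈0.03 kg on a
  0.58 kg change); it is user-overridable.
* **The beta for the RRR** is parameterised to make the mean exactly 0.27
  and the central 95% interval match (0.23, 0.30) in least squares over the
  concentration. The published interval is asymmetric the opposite way from
  a beta with that mean, so the fit carries a small documented residual
  (achieved interval ≈ (0.236, 0.305)); a moment-matching alternative
  (`beta_method = "moments"`) is exposed because it is not knowable which
  the original analysis used.
* **One-way sensitivity analysis** re-runs the deterministic chain at
  elasticities −1.0 and −0.8, holding the market calibration fixed at its
  base-case inversion: the calibrated volume is a market fact, the
  elasticity a behavioural parameter, so only the demand response varies
  and every decrease scales by ε/−1.14 exactly.

## Numerical choices

* kcal→kJ is fixed at 4.184 for the child equations (the 16.7 kJ/g ÷ 4
  kcal/g sugar constants imply 4.175; the difference is < 0.3% and the
  child equations are stated in kcal).
* BMI class intervals are right-half-open; the boundary values 23, 25 and
  30 classify upward, and are tested explicitly.
* The diabetes dose-response is linear proportional scaling (RRR·ΔBMI/2) by
  default, with a multiplicative option 1 − (1 − RRR)^(ΔBMI/2). At the BMI
  changes this model produces (≤ 0.33) the two differ by under 0.7
  percentage points of RRR (about 13–15% relative); linear is the default
  for transparency and exact linearity of the chain.
* Avoided cases are rounded to whole cases inside each Monte Carlo
  iteration, matching the deterministic definition; the rounding is visible
  only as a sub-case-level allowance in convergence checks.
* "Both sexes" estimates pool the strata with survey weights; they are not
  averages of the sex-specific estimates.
* Treatment costs: the complication share and the two unit costs are
  placeholders calibrated so the blended cost is 7,656,142 VND per case
  (the value implied by the published savings-to-cases ratio, ≈342
  USD/case); users with claims data should override all three.

## Design decisions that were genuinely open

* **Sugar-based tax reading.** The 60 VND sugar tax is interpreted as VND
  per gram of sugar contained per litre (density in g/100 ml × 10). Only
  this reading yields ≈6,600 VND/litre for carbonates and lands the 19%
  price rise next to the 7,000 VND/litre scenario's 20%.
* **Diabetes baseline application.** Applying the RRR to the overall 4.1%
  prevalence gives a 0.15 pp reduction for the 20% scenarios, whereas the
  published table prints 0.12 pp (and sex-specific 0.06/0.17 pp that no
  published combination of inputs reproduces — the sex-specific baseline
  prevalences are unpublished). The package does not force agreement: it
  exposes per-sex baseline overrides and keeps the transparent overall
  calculation as the default.
* **Child age weights.** The census age structure behind the published
  child averages is unpublished; uniform single-year weights over 2–17
  reproduce the published boys/girls values to their printed precision and
  are the default, with custom weights supported.

## Problem sizes

The shipped configuration mirrors the source survey (cohort n = 3,856) and
uses 10,000 Monte Carlo iterations. The test suite uses cohorts of
500–20,000 and 1,000–2,000 iterations, and the calibration checks use
n = 50,000, sizes at which the weighted class-share estimator's sampling
noise (≤ 0.2 pp SE) sits comfortably inside the 0.5 pp calibration band.

## Limitations

Only type 2 diabetes is modelled as a disease outcome, with a one-shot
steady-state burden calculation: no discounting, no mortality, no incidence
dynamics. Cross-price substitution (to diet drinks, water or untaxed
beverages), industry reformulation, tax revenue and SES/urban–rural
stratification are out of scope. Children get weight-change projections
only — no BMI classification, because height growth invalidates a fixed
height BMI projection. The energy-to-weight coefficients originate from
non-Asian populations and may approximate Vietnamese adults imperfectly;
they are fully configurable.
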