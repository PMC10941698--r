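---
title: "An individual-based model of contraception, pregnancy and family-planning costs"
author: "contrasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of contraception, pregnancy and family-planning costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrasim)
```

## The model

`contrasim` simulates individual women of reproductive age (15–49) moving
monthly among eleven contraception states: `not_using` plus ten methods
(pill, IUD, injection, implant, male condom, female sterilization, other
modern, periodic abstinence, withdrawal, other traditional). In each month a
woman takes exactly one of a set of exclusive transitions:

* **Not using**: she becomes pregnant with a monthly probability that
  depends on her single year of age, is multiplied by an HIV fertility
  multiplier if she is HIV positive and by a calibrated age-group scaling
  factor; or she initiates method $m$ with probability
  $\text{init}_m \times (1 + \text{agedev}(a)) \times \text{pop}_m \times
  \tau_I^{t}$, where $\text{agedev}$ is a proportional age deviation,
  $\text{pop}_m$ the demand-creation intervention multiplier and $\tau_I$ a
  per-year secular trend applied as $\tau_I^{\,t\text{ years since
  baseline}}$; or she stays. The outcomes are drawn as one categorical
  draw; if multipliers push the non-stay mass above 1 it is rescaled
  proportionally and the month is counted in `rescaled_months`.
* **Using method $m$**: sequentially, she experiences method failure
  (pregnancy) with probability $\text{fail}_m \times \text{rr}_{<25}
  \times \text{sf}(a)$; otherwise discontinues with
  $\text{disc}_m \times (1 + \text{agedev}_D(a)) \times \tau_D^{t}$;
  otherwise switches away with $\text{switch}_m$, the destination drawn
  from a row of the switch matrix; otherwise stays. Female sterilization is
  absorbing — it never discontinues or switches. The "failure first, then
  discontinuation, then switching" order implements the convention that
  switching probabilities are conditional on not discontinuing; the
  position of failure at the head of the sequence is this package's
  documented convention.
* **Pregnant**: a resolution event fires exactly nine calendar months after
  conception. With probability `live_birth_probability` (default 1 — early
  termination is decided outside this model's scope) a newborn enters the
  population; either way the woman's pregnancy ends and *in the following
  month* she initiates method $m$ with probability
  $\text{afterbirth}_m \times \text{ppfp}_m$ (the postpartum
  family-planning intervention multiplier), else returns to `not_using`.
  On conception a woman's method is set to `not_using` for the duration —
  a failure means the method has ended, and the paper-style state tables
  keep the pregnancy flag orthogonal to the method state.

Aging, mortality (annual probabilities converted monthly as
$1-(1-q)^{1/12}$), and the 15–49 eligibility window (evaluated at the
month's start; crossing 50 forces exit to `not_using`) complete the loop.
Because no woman is pregnant at the start, births in the first nine months
are scheduled directly from age-specific fertility rates: each woman is
assigned a birth with monthly probability ASFR/12 over a nine-month window,
uniformly placed in months 1–9, with conception backdated so the ordinary
resolution machinery delivers it.

## Parameters

`generate_default_parameters(seed)` builds a complete parameter set. The
scalar vectors with published Malawi values are embedded verbatim: HIV
fertility multipliers (1.4, 0.9, 0.8, 0.7, 0.5, 0.4, 0.3 by 5-year age
group), 2010–2014 age-specific fertility rates (0.144, 0.239, 0.213, 0.174,
0.123, 0.061, 0.022), pregnancy-risk scaling factors (1.227, 0.799, 0.829,
0.809, 0.749, 0.645, 0.941), the under-25 failure risk ratio 2.2, and the
maintenance intervals (IUD 4,383 days; implant 1,461; injection, condoms,
other modern and pill 91). The method-level tables are *synthetic*: the
full published probability tables live in an appendix that is not shipped
with this package, so we synthesize demographically plausible 2010-Malawi
tables instead — contraceptive prevalence around 26 percent of all women
15–49 with injection the dominant and highest-initiation modern method,
low IUD use, sterilization only above age 30 — and jitter them
reproducibly by seed. Anything estimated from data in the original study
is therefore a structural stand-in here, and the package's tests make
claims about *mechanics and recovery*, not about reproducing published
Malawi trajectories.

The sterilization age restriction is applied as a transform:
initiation below `eligible_age` (30) is zeroed and the eligible-age
probabilities are scaled up so the population-expected number of
sterilization initiations is preserved for the supplied age weights; within
each age the other methods are rescaled multiplicatively so the age's total
initiation probability is unchanged. The published description says only
that probabilities were "adjusted"; multiplicative rescaling is our
choice. For an age-constant input the scale factor reduces to
(total weight)/(weight at eligible ages); the implementation uses the
general mass-preserving form so the transform is idempotent-safe on
age-varying tables.

Age effects on initiation and discontinuation are stored as proportional
deviations with multiplier $1 + \text{value}$; after-birth initiation
carries no age effect. Secular trends are single per-year multipliers
$\tau_I$ (initiation, typically $> 1$) and $\tau_D$ (stopping, typically
$< 1$) applied as $\tau^{t}$ with $t$ in years since baseline; the exact
published functional form ("adjusted for older women") is appendix-only,
so the engine treats the trends as age-uniform and leaves age interaction
to the age-deviation curves.

Parameter bundles round-trip losslessly through CSV files (one per
parameter family, methods as columns, ages 15–49 as rows) with a
`manifest.csv`; `validate_parameters()` checks every structural rule and
reports all violations at once.

## Randomness and coupled runs

All randomness in `run_simulation()` derives from the configuration seed
through per-month, per-purpose substreams indexed by person id. Two runs
with the same seed but different interventions therefore see identical
uniforms person by person — common random numbers — even after their
populations diverge through differential births. Scenario contrasts
(with/without intervention) are then nearly noise-free: in the first
intervention month the set of initiating women under the intervention is a
superset of the baseline set by construction. Identical configurations
reproduce the event log byte for byte.

## Calibration

Calibration is two-stage, mirroring the model's structure:

1. **Scaling factors** (`fit_pregnancy_scaling_factors`): the expected
   monthly live-birth probability per age group, given the baseline method
   mix, is linear in the factor, so iterative proportional fitting
   (factor ← factor × target/achieved, target = ASFR/12) converges
   essentially in one pass; with a single age group and no contraception
   the fit equals the closed form $t/(b \cdot \text{lbp})$.
2. **Secular trends** (`fit_time_trends`): the two trend multipliers are
   fitted to a yearly births trajectory by coordinate descent with a
   Nelder-Mead polish, minimizing RMSD.

Both run on a deterministic *expectation-mode* companion of the engine
that propagates expected state fractions for 35 single-year female cohorts
(11 method states, a nine-month pregnancy pipeline, a postpartum slot)
with fixed cohort sizes and an annual age shift. This keeps the
calibration objective smooth and reproducible; it deliberately omits
demographic feedback (cohort growth, mortality) and HIV, which is
appropriate for fitting rates over one to two decades but not for
long-horizon population projection — final verification always reruns the
stochastic engine. Parameter recovery is the acceptance surface: trends
(1.02, 0.98) planted in a self-generated trajectory are recovered to
within 5 × 10⁻³, and fitted scaling factors reproduce the target fertility
schedule to machine precision.

`calibrate_intervention_multipliers` fits the Pop (and optionally PPFP)
multipliers by the same proportional-update idea against target method
shares at the simulation horizon. `rmsd_fit_percentage` expresses a
model-vs-reference RMSD as a percentage of the deviation between two
reference variants, the fit metric used for trajectory comparisons.

Defaults: relative tolerance 1 percent, at most 200 iterations.

## Costs

Each modern method has a consumable package (`cp_consumables()`) with
expected units per case and 2021 MWK unit prices; initiation appointments
add a pregnancy slide test. Pill and implant unit costs are weighted
averages over product alternatives (80/20 pill formulations → 493 MWK per
cycle; 50/50 two-rod/one-rod implants → 760 MWK; the implant interval is
the 50/50 average of five- and three-year products, 4 years = 1,461 days).
Costs accrue per appointment event: at initiation (including switches and
postpartum starts) and at maintenance appointments, which fire when the
days elapsed since the last appointment strictly exceed the method
interval. Simulation dates are whole months; elapsed months convert to
days at 365.25/12. Female sterilization accrues its package once at
initiation only. Women holding a method at the very start of a simulation
have no appointment on record and are charged an initiation appointment in
month 1; this only affects the startup year, far from the reporting
periods. Accounting is in real MWK with USD at 790 MWK/USD alongside;
display rounding (nearest 0.1 percent of women, nearest 1,000 users,
nearest million MWK) happens only in `print` methods. Implementation costs
of the two interventions are annual national amounts (2.4 billion and 264
million MWK in 2021 prices, taken as printed rather than re-inflated)
scaled each year by the simulated population aged 15–49 relative to the
2016 base. Personnel, facilities, equipment and stock-outs are out of
scope; consumables are assumed always available.

## Synthetic calendars and estimator recovery

`simulate_calendars` produces month-by-month event histories in the style
of survey contraceptive calendars (one code per month; a pregnancy is nine
`*` months, then `B`/`E`, then the postpartum outcome), generated by the
same step functions as the engine at baseline-date probabilities.
`estimate_monthly_probabilities` recovers the generating monthly
probabilities by occurrence-exposure estimation matched to the engine's
sequential convention: failures over using months, discontinuations over
using months that did not fail, switches over months that neither failed
nor discontinued, destinations as multinomial shares. The original study
estimated its tables from real survey calendars with competing-risks and
fractional-polynomial regressions; this module substitutes the simpler
discrete-time estimator because its purpose here is *round-trip
validation* of the simulator, not reproduction of published coefficient
tables. The recovery test uses a homogenised parameter set (age deviations
zero, scaling factors one, risk ratio one): with age effects active the
pooled estimand is an exposure-weighted mixture across ages rather than
the table parameter, and an age-stratified estimator would need far larger
samples. At 20,000 women over 60 months every generating probability is
recovered within three binomial standard errors.

## Reporting conventions

Method-mix shares include `not_using` and sum to one; the display
convention is the nearest 0.1 percent, and user counts scaled to a national
population round to the nearest 1,000. The dependency ratio counts
children 0–14 and adults 65 and over per adult 15–64; the published
caption says "over 65" while the conventional definition (and the quoted
national value) uses 65+, so this package uses ≥ 65 and notes the one-line
discrepancy here. Mid-year (June) population snapshots feed pyramids and
the dependency-ratio series.

## Problem sizes and determinism

The test suite and acceptance script use 20,000 agents for calibrated runs
and coupled scenario contrasts, 20,000 × 60 woman-months for estimator
recovery, 10⁶ draws for the transition-engine Monte Carlo, and one
50,000-agent, 40-year run to demonstrate scale; these sizes give standard
errors comfortably inside the tested tolerances while keeping a full test
run around two minutes. Every stochastic result is reproducible from a
single integer seed.

## Default study conditions

The default configuration simulates 2010–2050 with HIV prevalence 0.10
among women 15–49, a geometric age pyramid declining 3 percent per year of
age (a young, high-fertility population), and a mortality schedule with
elevated child mortality and Gompertz-like old-age mortality. These are
the package's fixed synthetic study conditions: plausible for the modeled
setting, not estimates of any particular year's vital statistics. Girls
aging into the 15–49 window enter HIV-negative and not using
contraception; HIV status is assigned once at initialization
(seroconversion dynamics are out of scope, and the HIV fertility
multiplier is a second-order effect on aggregate fertility here).

## Known limitations

* The method-level probability tables are synthetic; absolute levels of
  use, births and costs are internally consistent but not Malawi
  estimates.
* The expectation-mode model holds cohort sizes fixed, so fitted trends
  absorb (small) demographic-feedback effects when applied to the
  stochastic engine over long horizons.
* Pregnancies last exactly nine months; stillbirth typology, preterm
  birth and abortion care are out of scope, as are unmet-need modeling and
  wealth or education covariates.
* Men carry no contraception state (condom use is attributed to the
  female partner, as in survey calendars); they matter only for the
  dependency ratio and population-scaled implementation costs.

## A worked example

```{r, eval = FALSE}
p <- generate_default_parameters(seed = 1)
fit <- fit_pregnancy_scaling_factors(p, p$age_specific_fertility_rates,
                                     sim = cp_config(20000, 2010, 2035))
iv <- cp_intervention(pop = 3, ppfp = 2, start_year = 2023)
r0 <- run_simulation(cp_config(20000, 2010, 2035, seed = 1),
                     fit$parameters)
r1 <- run_simulation(cp_config(20000, 2010, 2035, seed = 1,
                               intervention = iv), fit$parameters)
summary(r1)
summarize_costs(r1, list("2023-2030"),
                cp_cost_config(base_population_15_49 = 5e6))
```
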