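---
title: "Methods: an integrated macro-demographic-health-environment simulation of fiscal food policy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated macro-demographic-health-environment simulation of fiscal food policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`cgehealth` implements a recursive-dynamic computable general equilibrium
(CGE) model with fully endogenous feedback loops between the macroeconomy
and four satellite modules: a nutrition module that maps solved household
food consumption into fatty-acid energy-intake shares; a biomarker module
that converts share changes into shifts of the Total:HDL serum cholesterol
ratio; a clinical module that converts stratified biomarker distributions
into myocardial infarction (MI) and stroke incidence, premature mortality,
disability, caregiver time and hospital costs; a cohort-component
demographic module; and a land-use-change (LUC) module for direct
greenhouse-gas accounting.  The flagship experiment is a product-specific
sales tax on palm cooking oil solved so that horizon-year per-capita energy
intake from palm oil falls by a configurable target (default 50%).

Because the calibration surveys behind such national models are rarely
deposited, the package ships a seeded synthetic-data generator that
produces every input the pipeline consumes with a known ground truth, so
calibration and simulation can be tested end to end by recovery.

## The economic core

**Within-period equilibrium.**  Each activity produces with Leontief
intermediates over CES value added in unskilled labour, skilled labour,
capital and (for primary crops) land.  Output transforms between exports
and domestic sales through a CET frontier; absorption combines imports and
domestic varieties through Armington CES aggregation.  The economy is a
small open economy: world prices are fixed, the real exchange rate adjusts
so the current account closes at an exogenous foreign-savings path.
Private demand is an Almost Ideal Demand System (AIDS) per regional
household, evaluated with the full translog price index anchored so
benchmark shares reproduce at unit prices.  The consumer price index is
the numeraire.

The solved system stacks zero-profit conditions, market clearing for
domestic varieties (one market dropped by Walras's law and reported as a
residual), factor-market clearing at full employment, the external
balance, the numeraire equation and one closure equation.  It is solved by
a damped Newton method in log prices and quantities with a
forward-difference Jacobian; tolerances are 1e-10 on scaled residuals.
Solutions warm-start from the previous period or the corresponding
baseline period, which keeps policy runs at two to three Newton steps.

**Closures.**  The counterfactual closure scales real government
consumption so the government consumption-to-absorption ratio stays at its
benchmark value, with savings-driven investment.  The policy closure is
iso-government: real government consumption follows the counterfactual
path (plus the endogenous hospital-cost delta), the government savings
path is held at the counterfactual, and the balancing instrument is a
uniform additive reduction in household direct-tax rates — the
sales-tax-revenue recycling rule.  Three compensating-transfer variants
(`iso_budget`, `iso_real`, `iso_both`) instead hold household nominal
budgets, household real consumption, or household and government real
consumption fixed by lump-sum transfers; lump-sum instruments were chosen
because they leave optimality conditions undistorted.

**Dynamics.**  Capital follows `K' = (1 - delta) K + real investment`
with `delta = 0.05/yr` and a benchmark service-flow-to-stock ratio of 0.1.
Labour endowments are derived each period from the working-age population
(ages 15 to the retirement age, default 65) times fixed participation
rates and a fixed skilled/unskilled split, minus patient and caregiver
worktime losses fed back from the health module.  The baseline solves one
Hicks-neutral productivity shifter per period so real GDP grows at 3.9%
p.a., and rescales the price level (a homogeneity-of-degree-one operation
that leaves the real allocation untouched) so nominal GDP grows at 6.2%
p.a.; both targets are met to 1e-6 or better.  Policy runs inherit these
shifters, so all policy impacts are deviations from a common
counterfactual.

**Within-period feedback fixed point.**  In policy runs the equilibrium,
intake shares, biomarker shift, clinical outcomes, labour losses and
hospital costs are iterated to a fixed point each period (relative change
below 1e-7 in the household cholesterol shifts, at most 50 sweeps; two to
three suffice in practice because the health feedback is small relative to
the economy).

## Nutrition and biomarker pathway

Per-capita/day energy is `sum_c q_ch e_ch / (365 pop_h)` with `q` real
consumption and `e` commodity- and household-specific energy densities.
SFA/MUFA/PUFA shares are percentages of total energy.  The cholesterol
response is the exact linear form

```
dC_h = 0.003 * dSFA_h - 0.026 * dMUFA_h - 0.032 * dPUFA_h
```

with deltas in percentage points measured against the *same-period
baseline* run.  The baseline-relative convention (rather than
lagged-actual) was chosen because reported policy impacts are differences
against the counterfactual; with it, the zero-tax scenario is identically
the baseline.  Because the source table prints only central coefficient
estimates, the confidence bounds used by the sensitivity machinery are
synthetic defaults (+-0.003 for SFA, +-0.012 for MUFA and PUFA) and are
configurable.  Energy-level changes are tracked and reported but do not
enter the cholesterol equation; only compositional change does.

Each household carries 10 equal-frequency support points of its pooled
cholesterol-ratio distribution.  A period's `dC` shifts every support
point additively and cumulatively (strata at `t` = strata at `t-1` plus
`dC_t`); frequencies never change.

## Clinical outcomes

Lookup tables are simulated at the 11 end-points of the 10 equidistant
sub-intervals of the ratio interval [2.0, 7.0]: for each disease x age x
gender x location cell, 10,000 individuals are drawn from the cell's
normal biomarker distribution recentred at each support value and their
mean risk recorded.  One normal sample is drawn per cell and reused across
support values (common random numbers), so monotone risk functions yield
exactly monotone tables.  Degree-10 polynomials interpolate the 11 values
exactly on the normalized domain [-1, 1] (the affine image of [2, 7],
chosen for Vandermonde conditioning; one step of iterative refinement
keeps node errors near machine precision).  Evaluations clamp inputs to
[2, 7] and outputs to [0, 1]; clamped strata are counted and logged as
warnings.

Incident cases are `sum_s freq_s x population x incidence(support_s)`;
premature deaths use the excess-mortality polynomials.  Years lost due to
disability are undiscounted person-years, cases x disability weight x
duration, with an acute duration for MI (0.02 yr) and a multi-year stroke
duration capped at the remaining horizon — matching the observed pattern
that MI disability burdens are tiny next to stroke burdens.  Caregiver
work and leisure time losses accrue per stroke case; hospital unit costs
are charged per case and paid from the government budget in the policy
closure (a config switch moves the payer to households).  Patient and
caregiver *work*-time losses reduce the labour endowment; leisure losses
are reported but not fed to the economy.

## Demography

The population state is counts by region x location x five-year band x
gender with 13 bands, the last open-ended (70+).  Thirteen five-year
bands ending in 70+ force the first band to start at age 10; ages 0-9 are
not modelled and births enter the first modelled band — a deliberate
stylization, acceptable because nothing downstream (risk, labour,
consumption) distinguishes ages below 15.  The projection is
annual: deaths are background mortality plus CVD excess deaths; births
apply fertility to female bands and enter the first modelled band; one
fifth of each band graduates per year; migration is region-redistributive
with zero national sum.  The identity `pop' = pop + births - deaths +
migration` holds exactly per region and location, which is what makes the
person-year ledgers audit cleanly.  Excess deaths are allocated to cells
in proportion to the model's own cell-level deaths; survivors of averted
deaths persist and age, generating the cumulative person-year gains a
policy run reports.

## Land use and emissions

Crop hectares follow the land factor employed by each crop activity at a
fixed benchmark hectares-per-land-unit conversion; since the land
endowment is fixed and fully employed, total cropland is conserved and net
losses always match net gains.  Period emissions allocate losses to gains
proportionally (no transition-preference data exist, so proportional
allocation is the neutral choice) and weight transitions by an
antisymmetric crop-to-crop coefficient matrix in t CO2-eq/ha, built from
per-crop carbon stocks.  Only direct LUC is computed.  A policy run's
first period is measured against the pre-policy benchmark allocation, so
the initial reallocation is counted.

## The synthetic data generator

The generator draws structural share parameters (input-output weights,
factor shares, household budget shares, trade intensities, tax and savings
rates) and solves the implied linear flow system, so the SAM is balanced
by construction; an income normalization pins the scale, which the budget
identities otherwise leave free.  Structure a practitioner would expect is
built in deliberately, because the policy experiment's qualitative
behaviour depends on it:

* palm cooking oil refines the oil-palm crop (about half its unit cost),
  other edible oils crush the annual crops, and primary crops feed only
  the food chains — structural zeros elsewhere — so a palm-oil demand
  shock propagates to oil-palm land;
* oil-palm fruit is not directly exported (it must be processed close to
  harvest) and households buy food crops, not the fruit;
* palm oil and other edible oils are gross substitutes (cross-price
  elasticity of other-oils demand with respect to the palm price drawn in
  0.40-0.50), the channel that shifts diets towards PUFA-dense oils when
  palm oil is taxed;
* fatty-acid profiles follow the actual oils: palm oil about 49% SFA /
  37% MUFA / 9% PUFA of energy, other oils a soybean/sunflower-like 10% /
  25% / 60%;
* oil palm carries a standing carbon stock of 110-140 t CO2-eq/ha versus
  18-26 for the annual crops, so conversion away from oil palm emits;
* budget shares of palm cooking oil are about 1.0% rural and 0.6% urban,
  energy densities are scaled so benchmark diets run near 2100
  kcal/person/day, and palm-oil own-price elasticities are drawn around
  -0.95 with income elasticities around 1.1.

Ground-truth AIDS parameters are constructed to satisfy adding-up,
homogeneity and symmetry exactly; the published elasticity priors are then
emulated by adding seeded noise to off-diagonal cross-price entries and
income elasticities (so regularity fails whenever noise is positive) and
lognormal cell noise to the SAM.  Risk functions are scaled logistic
curves in the cholesterol ratio with age-, gender- and location-specific
caps and midpoints — the simplest monotone bounded family, standing in for
an unavailable survey-based simulation model.  What the generator does
*not* emulate: measurement error correlated across tables, survey
weighting, seasonal diets, non-normal biomarker distributions, or any
behavioural response outside AIDS demand — so passing recovery tests shows
the estimators invert the generator's assumptions, not that they would
survive real survey pathologies.

## Calibration

SAM balancing minimizes the generalized cross-entropy
`sum(a log(a/p) - a + p)` subject to row-sum = column-sum, preserving
structural zeros; the first-order conditions reduce the problem to account
potentials solved by Newton on a Laplacian-like system.  The generalized
(unnormalized) divergence is used because it is stationary at a balanced
prior — the plain `a log(a/p)` form is not, and a balanced prior must pass
through unchanged.  Explicit account totals, when given, are imposed by
iterative proportional fitting instead.

AIDS regularity is imposed as a weighted least-squares projection
(Gaussian cross-entropy) of the prior parameters onto the linear
constraint set, solved exactly through the KKT system.  Divergence choice:
the signed parameters rule out the Kullback-Leibler form used for the SAM;
with the truth inside the constraint set, orthogonal projection can only
move the estimate towards it, which is the recovery property the tests
exercise.  Curvature (negative semidefiniteness of the Slutsky substitution
matrix) is not imposed; the generator draws own-price elasticities near -1,
where calibrated systems are well behaved over the simulated price range.

## Numerical choices and degenerate inputs

* Newton tolerance 1e-10 on scaled residuals; Walras residual audited
  below 1e-6 of GDP; institutional accounts close below 1e-8.
* Negative-price iterates are impossible in the log parameterization; the
  line search halves steps until the residual norm falls.
* The tax search brackets [0, 5] ad valorem and refines by safeguarded
  secant to 0.1% relative on the achieved intake reduction; an absent
  sign change raises an error pointing at the own-price elasticity.
* Degenerate cases are contract-checked: zero total energy is an error,
  excess deaths are capped at cell populations with a warning, retirement
  ages outside the supported 59-69 grid require an explicit override, and
  `delta = 1` with zero investment is rejected rather than producing a
  zero capital stock.

## Problem sizes

The default desk scale is 10 commodities, 4 regional households, 20
annual periods, 10 biomarker strata and 10,000 simulated individuals per
lookup cell; a `model_dims(scale = "full")` flag provides full national-model
study's dimensions (49 commodities, 9 households, 7 primary crops).  The
recovery experiments use 20 noisy replicates at noise level 0.1.  These
sizes keep a full tax-targeting experiment (baseline plus roughly a dozen
full dynamic solves) in the low minutes on a single core while leaving
every mechanism — including all feedback loops — switched on.

## Known limitations

* The health feedback is contemporaneous-only: no disease states, no
  post-stroke disability persistence, no discounting or age weights in
  the disability accounting.
* The demand system is calibrated, not estimated from micro records;
  priors are taken as given.
* Indirect land-use change, non-GHG environmental indicators and
  monetized externality valuation are out of scope.
* The synthetic economy reproduces the qualitative sign structure of the
  palm-oil experiment by construction of its defaults; its magnitudes are
  not comparable to any national study without real calibration data.
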