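---
title: "Methods: disaggregated EF1 factors and Monte Carlo N2O inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disaggregated EF1 factors and Monte Carlo N2O inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2oef)
```

## The problem

National greenhouse-gas inventories estimate direct soil N2O emissions from
nitrogen inputs with the Tier 1 emission factor EF1: the fraction of applied
N emitted as N2O-N. The 2006 IPCC Guidelines use a single EF1 of 0.010 with
a wide 95 % interval (0.003–0.030) for all soils, climates and fertilizer
forms. The 2019 Methods Refinement disaggregates EF1 by climate (wet vs dry)
and, within wet climates, by fertilizer form (synthetic and mixed vs
organic), which both shifts national totals and sharply narrows their
uncertainty. `n2oef` implements the full chain behind such a refinement:
deriving per-experiment emission factors from field studies, classifying
them by controlling factors, estimating disaggregated class means with
mixed models, and propagating the resulting triangular EF distributions
through a gridded Tier 1 inventory.

## Per-experiment emission factors and the study filters

Each observation is one fertilization experiment with cumulative N2O-N
fluxes on a treated and an unfertilized control plot over the same period:

$$EF_{1i} = \frac{N_2O_{Ti} - N_2O_{Ci}}{N_i}$$

with fluxes in kg N2O-N ha^-1 and the N input $N_i$ in kg N ha^-1. Negative
values are retained — control plots can out-emit treatments. Records are
excluded, with one machine-readable reason each, when they cannot inform
EF1: non-peer-reviewed sources, laboratory/greenhouse or modeling studies,
flooded rice (covered by the separate EF1FR factor), grazed urine/dung
deposition (EF3PRP), enhanced-efficiency fertilizers, drained or managed
organic soils, and records lacking a control plot or a positive N input.
Missing provenance flags pass with a warning rather than being silently
excluded, so the filter is auditable.

### Factor classification

Classes follow the conventions that make the factors usable with national
statistics:

* **Climate**: temperate/boreal wet where annual precipitation:PET > 1,
  tropical wet where annual precipitation > 1000 mm, otherwise dry. The
  defining inequalities are strict on both sides and leave exact equality
  open; `n2oef` assigns the boundary to the wetter class, configurable via
  `classify_climate(boundary =)`.
* **Fertilizer form**: pure organic vs synthetic-and-mixed (synthetic alone
  or any synthetic+organic mixture — their EF1 means are
  indistinguishable, so they pool).
* **N application rate**: left-open right-closed bins (0;100], (100;200],
  (200;300], >300 kg N ha^-1 period^-1.
* **Land cover**: annual croplands and bare soils (including crops recorded
  as "undefined", which sit in the bare-soil group) vs perennial systems
  (perennial crops, grasslands, agroforestry, tree plantations, managed
  forests).
* **Texture**: fine (sandy clay, silty clay, clay) vs medium and coarse
  (the other nine USDA classes).
* **Soil C**: < 2 % vs >= 2 % mass; **alkalinity**: pH < 7 vs >= 7;
  **experimental length**: <=120, (120;180], (180;240], (240;300], >300
  days; **irrigation**: a dry-climate-only contrast.

An observation missing one covariate is unclassifiable for that factor only
and still enters every other factor's model — which is why per-factor sample
sizes differ.

### Locations

Observations sharing an identical coordinate pair, or failing that the same
bibliographic reference with the same soil texture and raw land cover, are
one experimental location. The two rules are closed transitively
(union-find), coordinates taking precedence, and identifiers are stable
under row reordering. Locations are the random-effect grouping below.

## The per-factor mixed model

For each controlling factor the model is one-way with a location random
intercept, fitted by REML (via `lme4`):

$$EF_{ij} = \mu_{c(i)} + b_{\ell(i)} + \varepsilon_{ij}, \qquad
b_\ell \sim N(0, \sigma^2_L), \quad \varepsilon \sim N(0, \sigma^2_R)$$

Classes with n <= 20 are dropped before fitting; a factor with fewer than
two surviving classes is unanalyzable. Reported per class: the marginal
mean, its 95 % CI, and an LSD Fisher letter; per model: a Wald F test of
equal class means, R², and AIC.

Numerical and inferential conventions (each genuinely open, each
configurable or documented):

* **Degrees of freedom.** Residual df use a containment-style
  approximation, `df = n_obs - n_classes - (n_locations - 1)`, applied both
  to the CIs (`mean ± t(df, 0.975) × SE`) and to the LSD t tests.
* **LSD Fisher.** Unadjusted pairwise t tests on the estimated mean
  differences with standard errors from the fixed-effect covariance.
  Letters come from the insert-and-absorb algorithm, so two classes share a
  letter exactly when their difference is non-significant; when
  significance is intransitive a class carries several letters (an "AB"
  display). Letters are ordered by ascending mean, A lowest.
* **AIC** is computed from a maximum-likelihood refit, never from the REML
  objective, so models with different fixed effects compare fairly.
* **R²** is the squared Pearson correlation between observed EF and fitted
  values *including* the predicted random intercepts. The literature this
  mirrors is ambiguous about whether random effects are included; the
  choice here is documented, not asserted as anyone else's.
* **Variance components** from `lme4` are constrained non-negative; an
  estimated zero residual variance is a singular fit and an explicit error.
* Fixing `var_location = 0` reduces the fit to OLS exactly; this is the
  small-instance oracle route used throughout the tests.

`merge_classes()` automates the class-pooling workflow: candidate classes
merge iff all their pairwise LSD comparisons are non-significant, and the
decision record (p-values, direction) is returned for audit. Re-running on
merged output is a no-op.

## The Monte Carlo Tier 1 inventory

Grid cells carry synthetic and manure N masses (Gg N), a wet/dry climate
flag and a country code; flooded-rice N is expected to be removed upstream.
An EF scheme maps every (climate, component) stratum to a triangular
distribution. Two presets ship:

| scheme | stratum | lower | mode | upper |
|---|---|---|---|---|
| GL2006 | all N | 0.003 | 0.010 | 0.030 |
| MR2019 | dry, any form | 0.000 | 0.005 | 0.011 |
| MR2019 | wet, synthetic+mixed | 0.013 | 0.016 | 0.019 |
| MR2019 | wet, organic/manure | 0.001 | 0.006 | 0.011 |

The triangular parameterization takes the 95 % CI bounds of the
disaggregated EF1 as lower/upper and its mean as the mode. Point estimates
use the mode (mode × N reproduces the published Tier 1 arithmetic exactly);
CIs are the empirical 2.5/97.5 quantiles (linear interpolation between
order statistics) of the per-iteration aggregated totals.

Two design choices matter for the CI widths:

* **Draw sharing.** Each iteration draws *one* EF per stratum, shared by
  every cell in that stratum; draws are independent across strata. The EF
  is a systematic unknown, not a per-cell lottery: independent per-cell
  draws would average out across thousands of cells and collapse the
  global interval to a sliver, far narrower than any published uncertainty
  range for these inventories. GL2006 is deliberately a *single* stratum so
  the whole grid shares one draw.
* **Aggregation order.** Totals are summed draw-by-draw, so global =
  Σ countries = Σ cells holds at every iteration (conservation is tested at
  1e-9 relative tolerance), and country CIs are quantiles of sums, not sums
  of quantiles.

Emissions are reported in Gg N2O-N; `as_n2o_mass()` converts by 44/28 but is
never applied by default. Cell-scope CIs are opt-in (`cell_ci = TRUE`)
because they need the full draws-by-cells matrix.

## Synthetic data: what it emulates and what it does not

**EF observations.** The generator draws
`EF = class mean + location effect + residual` with Gaussian effects —
exactly the structure the mixed model assumes, which is the point: it
exists to exercise parameter recovery, CI coverage and the LSD/merging
machinery against a known truth. Defaults are the climate disaggregation
(wet 0.014, dry 0.005), variance components 2e-4 (location) and 4e-4
(residual), and a 49+16-location × 13-observation design giving n = 845
with 75 % wet observations — the size and wet-dominance of the published
compilations this emulates. Other covariates (80 % synthetic/mixed
fertilizer, 74 % of N rates below 200 kg N ha^-1, ~20 % missing soil C and
pH, 63 % of dry-climate observations irrigated) are drawn independently
from realistic marginals and are descriptive only: a single factor drives
the mean at a time, because a joint additive truth could not match each
one-way table's marginals simultaneously and the models fitted are one-way.
Raw fluxes are back-computed from the drawn EF against a fixed 1.0 kg
N2O-N ha^-1 control baseline — arbitrary, and harmless because only EF
enters downstream.

What the generator does *not* emulate: the right skew of real EF
distributions (a lognormal option exists for robustness experiments, but
the Gaussian default is what the model assumes), spatial autocorrelation,
and correlation between covariates (e.g. texture with climate). Passing
tests therefore demonstrate that the machinery is correct under its own
assumptions, not that those assumptions hold for any real compilation.

**Fertilizer grid.** Cells are split into countries, each country gets a
wet-cell propensity (Beta-distributed around the configured wet fraction,
so countries can be wet, dry or mixed), and per-cell N masses are lognormal.
When exact stratum totals are requested the masses are rescaled per stratum
to hit them exactly. `worked_example_grid()` is the deterministic 400-cell
calibration used throughout: its stratum totals (48,536 Gg wet synthetic,
21,084 dry synthetic, 24,350 wet manure, 9,040 dry manure; 103,010 Gg N
total) were solved from the published global Tier 1 points by equating
mode-EF arithmetic — 0.016 W + 0.005 (69,620 − W) = 882.0 for the synthetic
split and 0.006 W_m + 0.005 (33,390 − W_m) = 191.3 for manure. They are a
derived emulation, not anyone's measured wet/dry consumption split.

## Problem sizes and numerical tolerances

The packaged checks run at desk scale: 1e5–2e5 Monte Carlo iterations for
inventory intervals (the 97.5 % quantile of the GL2006 global total then
carries a Monte Carlo standard error of ~2–4 Gg on ~2,712 Gg), 1e6 draws
for sampler-vs-closed-form comparisons at 3 standard errors, 200 replicates
for CI coverage (expected in [0.90, 0.99]), 50 random small instances for
the LSD oracle, and 40 replicates per scenario for the merging behaviour.
The mixed-model recovery design (30 locations × 10 observations per class)
makes class-mean standard errors ≈ 2.8e-3, so the 0.016/0.006 contrast is
detectable but not trivially so.

Known numerical niceties: published lower CI bounds for the single-EF
scheme sit about 1 % above the analytic triangular quantiles (e.g. 539.1
printed vs 532.9 analytic for the global total, plausibly a Monte Carlo
resolution artifact in the original computation); `n2oef`'s tests assert
the analytic oracle. Near-zero variance components make the REML surface
flat and `lme4` may emit convergence chatter in that limit; estimates are
still at the boundary and the OLS route (`var_location = 0`) is exact.

## Limitations

One-way models only — no interactions, no meta-regression, no nonlinear
EF–N-rate response (countries with detailed rate data should fit their own
response curves). The inventory engine does not derive climate masks from
precipitation/PET rasters, reproject grids, or handle the flooded-rice and
grazing pathways; grid I/O is the tabular cell list. The location rule
cannot distinguish genuinely different sites that share rounded
coordinates.
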