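---
title: "Stratified gravity and radiation models for origin-destination trip matrices"
author: "odflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified gravity and radiation models for origin-destination trip matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odflow)
```

## The problem

District-level travel is often summarised as an origin-destination (OD)
matrix: the average number of trips per period from every district *i* to
every district *j*, inferred for instance from aggregated, anonymised
mobile-phone records. When such data are unavailable, spatial-interaction
models are used to estimate the flows. The workhorse is the gravity model,
which assumes flow grows with the population at both endpoints and decays
with the distance between them. In settings with strong heterogeneity —
a dominant capital, large rural hinterlands, administrative regions that
concentrate routine travel — a single parameter set for all trips misses
systematic structure: short intra-regional and rural-to-rural flows behave
differently from long inter-regional or urban-to-urban ones.

`odflow` implements the stratified-gravity approach: the model's parameters
are fit separately *per trip type*, where a trip's type is defined by the
urbanicity of its endpoints, by whether it stays inside one region, or both.
A finite-system radiation model is included as a parameter-light
alternative, and all models are compared on one Bayesian footing.

## Models

### Gravity variants

The expected flow from district $i$ (population $P_i$) to district $j$ at
centroid distance $d_{ij}$ km is

$$\hat T_{ij} = \theta\, P_i^{\alpha_c}\, P_j^{\beta_c}\, f_c(d_{ij}),$$

with a power kernel $f_c(d) = d^{-\gamma_c}$ or an exponential kernel
$f_c(d) = \exp(-d / D_c)$, where $c$ is the trip category of the ordered
pair $(i, j)$. Both kernels are *decaying*: $\gamma_c \ge 0$ is a decay
exponent and $D_c > 0$ a deterrence distance in km, so trips decrease with
distance — the distance term is a penalty. Four stratification schemes are
supported:

| scheme | categories | index |
|---|---|---|
| basic | 1 (all trips) | — |
| urbanicity | 4: rural→rural, rural→urban, urban→rural, urban→urban | k = 1..4 |
| regional | 2: intra-regional, inter-regional | m = 1..2 |
| regional-urbanicity | 8: the full cross | n = 4(m−1)+k |

The proportionality constant $\theta$ is *shared* across categories: only
$\alpha$, $\beta$ and the decay parameter are stratified. This is an
identifiability choice — a per-category constant would be confounded with
per-category exponents on these data — and it keeps the nested structure
clean (with all per-category parameters equal, every stratified model
reduces exactly to the basic one; `gravity_predict()` satisfies this
identity to machine precision and the test suite asserts it).

The combined index enumerates intra-regional categories 1–4 and
inter-regional 5–8, in the same urbanicity order as k. This ordering is
declared in every typology export (`write_typology()`), since the
correspondence between index and label is a convention, not a property of
the model.

A district is *urban* when its fraction of urban grid cells strictly
exceeds the threshold (default 0.5; 0.1 is a common sensitivity setting).
Ties go to rural: "more than half urban" is taken literally.

### Radiation model

The finite-system radiation model sends $T_i = \sigma P_i$ trips out of
each origin and distributes them by intervening opportunity:

$$\hat T_{ij} = \frac{\sigma P_i}{1 - P_i / P}\;
  \frac{P_i P_j}{(P_i + s_{ij})(P_i + P_j + s_{ij})},$$

where $P$ is the total population and $s_{ij}$ the population living closer
to $i$ than $j$ does, excluding both endpoints. `odflow` computes $s_{ij}$
from centroids by the cumulative definition: districts strictly closer to
the origin than the destination contribute their full population, with
distance ties broken deterministically by district order. A polygon-based
definition (districts partially inside the circle of radius $d_{ij}$)
would need boundary data and an arbitrary partial-inclusion rule; the
cumulative definition needs neither and preserves the finite-system
normalisation *exactly*: every predicted row sums to $\sigma P_i$
identically (a telescoping identity the tests assert at `1e-10` on random
geographies).

$\sigma$ is nominally the proportion of the population travelling per
period, but because the observations are average trip counts it can
legitimately exceed 1 (several trips per person per month); the
implementation therefore only requires $\sigma > 0$.

## Fitting and model comparison

Observed counts $m_{ij}$ are modelled as independent Poisson draws,
$m_{ij} \sim \text{Pois}(\hat T_{ij})$. Within-district travel is never
modelled: the diagonal is structurally absent. Routes recorded as `NA` are
treated as missing (distinct from observed zeros, which stay in the
likelihood); non-integer averages are rounded to the nearest integer with a
message; districts with no trip data at all are dropped before fitting and
named in the log.

All parameters receive independent Gamma(0.001, 0.001) priors — the
conventional uninformative choice for positive parameters, configurable via
`mcmc_control(prior_shape=, prior_rate=)`. Sampling is by a full-block
random-walk Metropolis on the log scale:

1. **Laplace initialisation.** The posterior mode is found by BFGS with the
   analytic gradient; the inverse Hessian gives the initial proposal
   covariance. (Every gravity variant is log-linear in transformed
   parameters, so the mode-finding problem is smooth and fast.)
2. **Burn-in adaptation.** The scalar step size adapts towards a 23.4%
   acceptance rate; halfway through burn-in the proposal covariance is
   re-estimated from the burn-in draws, which protects against a
   misleading curvature estimate when a parameter is weakly identified.
3. **Frozen sampling.** After burn-in both the step size and covariance are
   fixed, so the retained draws come from a valid Metropolis chain.

Defaults are 2 chains, 2,000 burn-in iterations, 5,000 retained draws at
thinning 5, seed 1234 (chain $c$ uses `seed + c − 1`; a fit is exactly
reproducible given its control). Convergence is summarised by split-$\hat R$
per parameter — a warning (never silent) fires above 1.1 — and a
autocorrelation-based effective sample size.

The deviance $-2\log L$ is recorded at every retained draw. Models are
compared by the Deviance Information Criterion in Spiegelhalter's form:
$p_D = \bar D - D(\bar\vartheta)$ evaluated at the posterior means, and
$\mathrm{DIC} = \bar D + p_D$. `rank_models()` orders fits by DIC (ties
broken in favour of fewer parameters) and reports the percent change
against the basic model, $100\,(\mathrm{DIC}_{basic} -
\mathrm{DIC}_{model})/\mathrm{DIC}_{basic}$, so improvements are positive.
The radiation model's Bayesian fit is conjugate (Gamma prior × Poisson
likelihood in $\sigma$), so its posterior is sampled exactly and its DIC
lives on the same scale as the gravity fits'.

Beyond global fit, `ratio_accuracy()` summarises the ratio of predicted to
observed counts per trip type and the fraction of routes whose prediction
falls within ±10% (configurable) of the observation. Routes with an
observed zero have an undefined ratio; they are excluded from these
summaries and counted separately — a reporting choice, flagged in the
output, since ratios spanning many orders of magnitude otherwise hinge on
how zeros are patched.

## The synthetic-data generator

Real CDR-derived OD matrices are proprietary, so the package ships a
generator (`generate_geography()`, `generate_trips()`,
`make_benchmark_suite()`) that emulates their statistical structure:

* regions are spatial clusters — region centres uniform in a bounding box,
  district centroids Gaussian-jittered around them, so intra-regional
  distances are stochastically smaller than inter-regional ones;
* district populations are log-normal (median $10^5$, log-sd 0.9) with the
  largest district scaled ×8 as a capital;
* urban labels go to each region's most populated districts until a 30%
  share is reached. Concentrating urbanicity in large districts while
  spreading it across regions matters: if the *globally* largest districts
  were urban, log-population would be nearly constant within urban-urban
  trip categories and their $(\alpha, \beta, \gamma)$ would sit on a
  likelihood ridge;
* observed counts are independent Poisson draws at the model's expected
  values — the models' own noise assumption. No overdispersion is added in
  this version.

The default desk scale is 4 regions × 8 districts (992 ordered routes),
which keeps a full five-model comparison with the default MCMC settings in
the tens of seconds on one core. The benchmark suite builds three worlds on
one shared geography: a basic-gravity world ($\alpha=0.9$, $\beta=0.7$,
$\gamma=1.5$, $\theta$ calibrated to a median expected count of 50), a
regional-urbanicity world with well-separated decay exponents (intra
0.5–1.4, inter 1.7–2.6, so travel concentrates within regions), and a
radiation world ($\sigma = 0.2$). For the stratified world $\theta$ is
calibrated so the *weakest* category's median expected count is 20
(`calibrate_theta(per_category = TRUE)`): with a shared $\theta$ and decay
exponents spanning two units, an overall-median calibration can leave the
fastest-decaying category with essentially zero counts and its parameters
unidentifiable. The resulting totals are large (order $10^8$ trips), which
is the deliberate price of giving every one of the eight categories usable
signal.

What the generator does *not* emulate: mobile-phone ownership and coverage
biases, tower-to-district assignment error, seasonality, or overdispersed
counts. Passing tests on synthetic data therefore demonstrates that the
estimators recover the models' own parameters and rankings under the
models' own noise assumption — not that the models describe any particular
country's travel.

## Numerical and design notes

* Distances are haversine great-circle distances on a sphere of radius
  6371.0 km (the conventional mean Earth radius; the distance matrix is
  symmetrised and its diagonal set to exactly zero).
* GeoJSON polygons, when used, are reduced to the standard shoelace area
  centroid — not the vertex mean, which is biased for irregular polygons.
* Aggregation to coarser units (`aggregate_geography()`, for
  areal-unit-sensitivity analyses) sums populations, population-weights
  centroids and urban fractions, sums member-pair trips, and drops trips
  that become within-unit. An aggregated unit inherits the region of its
  most populous member; population and between-unit trips are conserved
  exactly.
* The power kernel is singular at zero distance, so coincident centroids
  of distinct districts are an error for that kernel.
* Fitting a stratified scheme requires every category to contain at least
  one observed route; otherwise the fit aborts with the offending
  categories named.
* With near-flat Gamma priors, a parameter that the data drive towards
  zero makes the log-scale posterior extremely heavy-tailed; the fit will
  complete but flag large $\hat R$. This is usually a sign that a category
  lacks the variation needed to identify its parameters.

## Limitations

The package fits the models above and nothing more: no ensemble
combinations, no covariate-augmented gravity variants, no
radiation-with-selection, no temporal dynamics. DIC is the only
model-selection criterion offered, for comparability within one dataset;
DIC values fitted to different datasets are not comparable.
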