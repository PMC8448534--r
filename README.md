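# odflow

Stratified gravity and radiation models for origin–destination (OD) trip
matrices.

`odflow` is for epidemiologists, demographers and transport modellers who
work with district-level travel data — typically average monthly trip
counts between administrative units, as aggregated from mobile-phone call
data records — and need spatial-interaction models that respect the
heterogeneity of such settings: a dominant capital, large rural areas, and
travel concentrated within administrative regions.

## Models

The core model family is the gravity model with *trip-type-stratified*
parameters. The expected flow from district *i* to district *j* is

    T_ij = theta * P_i^alpha_c * P_j^beta_c * f_c(d_ij)

where `P` are district populations, `d_ij` the haversine distance between
centroids (km), and `f_c(d) = d^(-gamma_c)` (power kernel) or
`exp(-d/D_c)` (exponential kernel). The category `c` of an ordered pair is
defined by one of four schemes: **basic** (one category), **urbanicity**
(rural/urban origin × destination, 4 categories), **regional**
(intra/inter-regional, 2), or **regional-urbanicity** (their cross, 8).
`theta` is shared; `alpha`, `beta` and the decay parameter are fitted per
category.

A finite-system **radiation model** is included as a parameter-light
alternative: `T_ij = sigma*P_i/(1-P_i/P) * P_i*P_j /
((P_i+s_ij)(P_i+P_j+s_ij))`, with `s_ij` the population intervening
between *i* and *j*.

All models are fitted to observed counts under a Poisson likelihood,
`m_ij ~ Pois(T_ij)`, by MCMC with uninformative Gamma priors, and compared
by the Deviance Information Criterion (DIC) plus per-trip-type accuracy
(share of routes predicted within ±10% of the observation). A synthetic
data generator produces CDR-like geographies and trip matrices with known
parameters, so the whole pipeline is testable without proprietary data.

## Worked example

Simulate a basic-gravity world, fit the basic model and a radiation model,
and compare them:

```r
library(odflow)

sc <- make_benchmark_suite(seed = 1)$basic   # 32 districts, known parameters
sc$true_params
#> Gravity parameters: basic scheme, power kernel
#>   theta: 0.001636
#>  category alpha beta gamma
#>       all   0.9  0.7   1.5

fit <- fit_gravity(sc$trips, sc$geography, sc$typology,
                   scheme = "basic", kernel = "power",
                   control = mcmc_control(seed = 42))
summary(fit)
#> Posterior summary (basic scheme, power kernel)
#>         mean     sd   2.5%    50%  97.5%   rhat      ess
#> theta 0.0017 0.0000 0.0016 0.0017 0.0018 0.9999 2983.807
#> alpha 0.8983 0.0009 0.8965 0.8983 0.9001 1.0006 3126.076
#> beta  0.6984 0.0011 0.6962 0.6984 0.7007 0.9999 2884.986
#> gamma 1.5019 0.0015 1.4990 1.5018 1.5048 1.0003 3133.817
#> DIC: 6997.3239  p_D: 3.938  acceptance: 0.194/0.183

rad <- fit_radiation(sc$trips, sc$geography, method = "bayes",
                     control = mcmc_control(seed = 42))
rank_models(list(basic = fit, radiation = rad))
#>       model        dic      p_d n_params rank pct_change_vs_basic
#> 1     basic   6997.324 3.937940        4    1                0.00
#> 2 radiation 850420.739 1.020145        1    2           -12053.51
```

The posterior recovers the generating parameters (`alpha` 0.9, `beta` 0.7,
`gamma` 1.5) to three decimals with an effective parameter count `p_D` of
about 4 — the model's actual dimension — and the misspecified radiation
model is (rightly) ranked far behind on these data.

The same interface fits the stratified schemes
(`scheme = "urbanicity" | "regional" | "regional_urbanicity"`, either
kernel); `evaluate_models()` adds per-trip-type ratio and ±10% accuracy
tables; `run_pipeline()` goes from CSV (or simulated) inputs to a full
report directory, and `exec/odflow` wraps it for the shell
(`odflow run-all --out results --seed 1`).

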