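# apcmech

Mechanism-based (front-door) identification of age-period-cohort effects.

## The problem

Decomposing an outcome into effects of age (*A*), calendar period (*P*) and
birth cohort (*C*) is unidentified: because *A* = *P* − *C*, the regression

> E(Y | A, P, C) = η + α·A + β·P + θ·C

has infinitely many solutions, and conventional APC estimators pick one by
an arbitrary technical constraint. The mechanism-based approach instead
identifies the causal parameters (α\*, β\*, θ\*) through Pearl's front-door
criterion: when a complete set of mediators M₁, …, M_K transmits *all* of
one dimension's effect (say, period), two regression stages —

1. each mediator on period: `M_k = γ₀ + γ₁·P + ν`,
2. the outcome on age, cohort and the mediators:
   `Y = δ₀ + δ₁·A + δ₂·C + Σ δ₃k·M_k + ξ`

— recover everything. α\* and θ\* are the outcome-model coefficients, and
the period effect is recovered by **path tracing**: the effect along each
pathway P → M_k → Y is the product γ̂₁k·δ̂₃k, summed over pathways. The rule
is valid for linear and probit models without product terms; for logistic
links or interactions the package provides the **Monte Carlo front-door
extension**, which simulates mediators and potential outcomes from the
fitted models over *independently drawn* (ã, p̃, c̃) values — breaking the
linear identity — and refits an identifiable APC dummy regression to the
simulated records.

The package is aimed at demographers and epidemiologists who want to (a)
apply the mechanism-based estimators to individual-level data, (b) reason
about the bias that omitted mediators, multi-cause mediators and
mediator-outcome confounding induce through the APC identity (closed forms
included), and (c) run calibrated simulation studies of those biases on a
synthetic cardiovascular-mortality population.

## What's in the box

| module | exported surface |
|---|---|
| categorization | `apc_scheme()`, `apc_categorize()`, `apc_dummy_encode()`, `validate_identity()` |
| data container / IO | `apc_dataset()`, `read_apc_data()`, `write_apc_data()`, `drop_mediators()` |
| synthetic generator | `scenario_config()`, `calibrate()`, `generate_apc_data()`, `attribution_shares()` |
| path tracing | `fit_mediator_models()`, `fit_outcome_model()`, `path_trace()`, `estimate_pathtrace()`, `delta_method_se()` |
| Monte Carlo front door | `mc_config()`, `simulate_mediators()`, `simulate_outcomes()`, `fit_apc_on_simulated()`, `estimate_mcfrontdoor()` |
| uncertainty | `apc_bootstrap()`, `bootstrap_mc()` (percentile intervals) |
| bias theory | `expected_coeffs()`, `omitted_mediator_bias()`, `verify_against_ols()` |
| experiments | `experiment_spec()`, `run_experiment()`, `experiment_trends()`, `vary_effect_sizes()`, `report()` |

A thin command-line interface (`exec/apcmech`) exposes `simulate`,
`estimate`, `bias` and `experiment` subcommands over the same functions.

The synthetic population covers ages 40–95 in calendar years 1990–2015,
categorized into five-year groups (11 age × 5 period categories and 15
overlapping cohort categories, i.e. 10/4/14 identifiable dummy variables),
with CVD death as the outcome and four period mediators — an `unmeasured`
pool, BMI, smoking and statin use — whose sign structure makes the net
period effect negative. Age carries 70% of the APC effect, the
period-mediated pathways 20% (40% of it through the unmeasured pool) and
cohort 10%. Three scenarios (`simple`, `more_causes`, `confounding`) and
three variants (probit, logistic, linear) isolate the failure modes of the
approach. See the methods vignette
(`vignettes/mechanism-based-apc.Rmd`) for the calibration details and
design decisions.

## A worked example

```r
library(apcmech)

cfg <- scenario_config("simple", "probit", n = 20000, seed = 1)
dat <- generate_apc_data(cfg)
estimate_pathtrace(dat)
#> APC effect estimates (pathtrace estimator, probit)
#>   note: probit products are latent-scale approximations for binary mediators
#>   age     trend +0.2046 per category (11 categories)
#>   period  trend -0.6735 per category (5 categories)
#>   cohort  trend -0.1132 per category (15 categories)
```

Age effects rise steeply across the 11 five-year categories, the mediated
period effect falls by about 0.67 probits per five-year period (driven by
the negative unmeasured/smoking/statin pathways), and cohort effects drift
weakly downward. Dropping the unmeasured mediator — 40% of the period
pathways — reattributes its negative path products to age and cohort
through the identity:

```r
est_b <- estimate_pathtrace(drop_mediators(dat, "unmeasured"),
                            mediators = c("bmi", "smoking", "statin"))
#> cohort trend, full mediator set:  -0.113
#> cohort trend, unmeasured dropped: -0.210
```

exactly the direction `omitted_mediator_bias()` predicts. Bootstrap
uncertainty for any estimator:

```r
apc_bootstrap(dat, function(d) estimate_pathtrace(d), B = 50, seed = 2)
#>    dimension category estimate    se ci_lo ci_hi
#> 13    period        2    -0.53 0.060 -0.63 -0.43
#> 14    period        3    -1.30 0.089 -1.50 -1.17
#> 15    period        4    -2.12 0.125 -2.34 -1.92
#> 16    period        5    -2.57 0.144 -2.81 -2.36
```

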