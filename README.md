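# ecenest

Developmental-window exposure to extreme climatic events (ECEs) and its
consequences for nestling fitness in cavity-nesting birds.

Long-term nestbox studies (the motivating system is a great tit *Parus
major* population breeding April–June in temperate woodland) record, for
every brood, the lay date, hatch date, clutch size and the mass of each
chick at day 15 ("fledging mass"), plus whether each fledgling later
recruited to the local breeding population. `ecenest` links those records to
a daily climate series and asks how rare temperature and rainfall extremes
during two developmental stages — the hatchling stage (days 0–7 post-hatch,
before homeothermy) and the nestling stage (days 8–15, peak energetic
demand) — relate to fledging mass and recruitment.

## What the package computes

**ECE definition.** Daily deviations from a monthly climate baseline are
computed for temperature and rainfall; an ECE is a day in the extreme tail
of the deviation distribution over the full study span. For tail
probability *p* (default 0.05, with 0.01 as the "very extreme" variant):

- hot ECE: temperature deviation ≥ the (1 − *p*) quantile,
- cold ECE: temperature deviation ≤ the *p* quantile,
- rain ECE: rainfall deviation ≥ the (1 − *p*) quantile,

with quantiles by linear interpolation of order statistics and inclusive
comparisons; consecutive extreme days each count as separate events. A
brood-specific ±15-day window baseline is available as a sensitivity
variant.

**Exposure.** For each brood and stage window the package counts flagged
days (`n_hot`, `n_cold`, `n_rain`), derives binary presence, and averages
the ambient temperature and rainfall over the same days.

**Inference.** Per-chick mixed models with crossed random intercepts for
year, brood, mother and nestbox, fitted by REML (Gaussian fledging mass)
or Laplace ML (binomial recruitment) via lme4:

    mass_ij = β₀ + β·x_ij + u_year + u_brood + u_mother + u_nestbox + ε_ij

where the fixed terms x may include ECE counts, natural cubic splines of
stage mean temperature (df = 5), ECE × ambient-weather and
ECE × relative-lay-date interactions (including a quadratic count
interaction), and categorical ECE levels ("0", "1", …, "4+") for the
recruitment models. All fixed effects are standardized (mean 0, SD 1), so
coefficients are comparable effect sizes; inference is Wald with a normal
reference. A path analysis decomposes the total lay-date effect on mass
into a direct path and indirect paths through stage temperature and ECE
exposure (indirect = product of path coefficients; total = direct + Σ
indirect, an exact OLS identity). Generalized variance-inflation factors
check multicollinearity.

**Synthetic data with known truth.** Because such life-history datasets are
not freely redistributable, the package ships a generator that emulates the
whole system — seasonal AR(1) temperature, Bernoulli-gamma rainfall, brood
phenology with mother/nestbox reuse, and chick outcomes drawn from the same
linear predictors the models fit, with configurable coefficients set near
published effect magnitudes (rain-event effect −0.143 SD, lay-date effect
−0.223 SD, mass median 18.5 g, recruitment 9.1%). Every analysis stage is
validated by parameter recovery against that truth.

## Worked example

```r
library(ecenest)

study <- simulate_study(seed = 42)   # 20 years x 50 broods
study$thresholds
#> ECE thresholds (5% tails, calendar_month_longterm baseline, 7305 days 2001-01-01..2020-12-31)
#>   hot  >= +5.17 C   cold <= -5.21 C   rain >= +9.26 mm

summarize_dataset(study$analysis)
#> # A tibble: 1 x 7
#>   n_chicks n_broods n_years mass_median_g mass_q25_g mass_q75_g recruitment_fraction
#>      8541     1000      20          18.4       17.5       19.4                0.110

fit <- fit_preset(study$analysis, "ece_count_rain_nestling")
tidy(fit)
#>                term estimate std.error statistic  p.value conf.low conf.high
#>         (Intercept)   18.442    0.1165    158.36 0.00e+00  18.2142    18.671
#>     nestling_n_rain   -0.207    0.0276     -7.49 7.14e-14  -0.2606    -0.152
#>  nestling_mean_temp    0.149    0.0317      4.70 2.62e-06   0.0867     0.211
#>             lay_doy   -0.317    0.0273    -11.58 5.00e-31  -0.3704    -0.263
#>         clutch_size    0.116    0.0262      4.44 8.98e-06   0.0649     0.167
```

The thresholds are the calibrated 5%-tail cutoffs on this synthetic series.
The rain coefficient says one standard deviation more rain ECEs during the
nestling stage predicts a 0.21 g lighter chick (≈ −0.148 in latent SD
units, generated truth −0.143), holding stage temperature, lay date and
clutch size fixed, with year/brood/mother/nestbox heterogeneity absorbed by
the random intercepts. `tidy(fit, "ran_pars")`, `glance(fit)`,
`autoplot(fit)`, `predict_response()` and `plot_exposure_response()` give
variance components, fit summaries, coefficient and prediction plots.

To analyse real data instead, read it with `read_daily_climate()` (columns
configurable via `climate_dialect()`) and `read_brood_table()` (schemas:
`brood_id,year,lay_doy,hatch_date,clutch_size,mother_id,nestbox_id` and
`chick_id,brood_id,mass_d15_g,recruited`), then either call the stage
functions directly or run every preset of the model roster in one shot with
`run_pipeline(pipeline_config(...))`, which writes a self-describing run
directory. A thin command-line wrapper with per-stage subcommands is in
`inst/exec/ecenest-pipeline.R`.

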