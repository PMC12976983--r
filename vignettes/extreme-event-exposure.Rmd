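---
title: "Extreme-event exposure and nestling fitness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme-event exposure and nestling fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecenest)
```

`ecenest` analyses how extreme climatic events (ECEs) experienced during
two nestling developmental windows relate to fledging mass and local
recruitment in a long-term nestbox study. This vignette is the package's
account of the science: the definitions and models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices behind the code.

## 1. Defining extreme climatic events

The raw environmental input is a daily series of mean air temperature
(°C) and 24-h rainfall totals (mm). Because "extreme" is relative to the
time of year, days are first expressed as deviations from a monthly
baseline, and an ECE is a day whose deviation falls in a chosen tail of the
long-term deviation distribution.

**Baseline.** Two baseline modes are implemented.

* `calendar_month_longterm` (default): one mean per calendar month, pooled
  over all years. A deviation then mixes "unusual for the season" with
  "unusually warm/cold year", which is what a bird experiences relative to
  the long-term norm.
* `month_within_year`: a mean per year-month, so deviations are purely
  within-month anomalies.

The default was chosen because the sensitivity variant described below is
contrasted against *calendar* monthly means, implying the calendar-month
pooling is the reference definition; both modes are first-class and every
derived object records which mode produced it.

**Thresholds.** For tail probability $p$ the cutoffs are

* hot: the $(1-p)$ quantile of temperature deviations,
* cold: the $p$ quantile (stored signed, i.e. negative),
* rain: the $(1-p)$ quantile of rainfall deviations,

computed by linear interpolation between order statistics
(`stats::quantile()` type 7). Median-unbiased quantile definitions differ
only at the third decimal at climatological sample sizes (about 22,000
days), but the convention is recorded in the threshold object so printed
cutoffs are interpretable. Day classification is inclusive (`>=` / `<=`),
so a day exactly at the cutoff is an event, and consecutive extreme days
each count as separate events — persistence is part of the exposure, not
collapsed into one "spell". Thresholds are calibrated once on the full
configured span, never per year, with defaults $p = 0.05$ and a "very
extreme" variant $p = 0.01$. Two structural consequences are tested as
invariants: the 1%-tail flags are a subset of the 5%-tail flags, and
shrinking the tail can never increase a window count.

**Brood-specific sensitivity variant.** As an alternative to the monthly
baseline, each brood's temperature baseline can be the long-term mean over
its own developmental window extended by ±15 days, taken at the same
calendar days in every year of the series. This removes the step
discontinuities of calendar months. Only temperature events are recomputed
under this variant by default (the rainfall definition keeps the monthly
baseline), and on synthetic data the brood-level counts from the two
definitions agree strongly (Pearson r above 0.8, equal count levels). The
agreement on the package's synthetic data sits slightly below the
correlations reported for real long-series data: with 8-day windows the
counts are small integers, and the flags that flip between methods are
precisely the marginal days near month edges where the step and smooth
baselines differ most, which caps the attainable correlation. This is a
property of the emulation scale, not of the implementation; the per-brood
baselines themselves are verified against a direct averaging oracle to
1e-10.

## 2. Developmental windows and exposure

Two stage windows are defined relative to hatch (day 0), endpoints
inclusive: the *hatchling* stage, days 0–7, when chicks are effectively
ectothermic; and the *nestling* stage, days 8–15, with improved
thermoregulation but peak energetic demand, ending at the day-15 weighing.
Descriptions of "full hatchling exposure" in terms of six consecutive days
exist in the literature for this system; the package keeps the explicit
0–7/8–15 windows as defaults and makes the offsets configurable rather than
guessing at an alternative, since every downstream quantity (counts,
binaries, ambient means) is defined per configured window.

Per brood and window the package counts flagged days, derives binary
presence (`any_x` if and only if `n_x >= 1`, a tested invariant), and
averages raw temperature and rainfall over the same days, so ambient
conditions are matched to exactly the days each brood experienced. Days
missing from the climate series are *gap days*: excluded from counts and
means, reported per window, flagged for exclusion when they exceed 25% of
the window, and an entirely-gapped window is an error naming the brood.
Exposure is computed by a vectorised join; a brute-force day-by-day loop
over 1000 random broods reproduces it exactly in the test suite.

## 3. Breeding data

The biological input is a brood table (lay day-of-year, hatch date, clutch
size, mother and nestbox identifiers; first clutches only) and a chick
table (day-15 mass in grams, recruitment 0/1). *Relative lay date* is the
brood's lay date minus the unweighted mean lay date of the included broods
of its cohort year — unweighted because lay date is a brood property, so a
chick-weighted mean would let large broods drag the reference. The mean
(not the median) is the default population average, with the median
available by option. Seasonal percentile groups label broods *early* (at or
below the 15th within-year percentile of relative lay date) or *late* (at
or above the 85th), cutoffs inclusive on both sides; a brood satisfying
both (possible under heavy ties) is labelled early and a warning notes the
tie; years with fewer than three broods are labelled mid. The analysis
table joins chicks to broods and both stage windows' exposure records with
no silent drops: row conservation is tested, and every exclusion (gap
flagging, the carry-over filter that restricts nestling-stage models to
chicks with zero hatchling events of the same type) is listed on the
result.

## 4. Models

All models are per-chick mixed models with crossed random intercepts for
birth year, brood, mother and natal nestbox, the grouping factors that
induce non-independence among chicks. Fledging mass models are Gaussian,
fitted by REML; recruitment models are binomial (logit link), fitted by
Laplace maximum likelihood. Fitting is delegated to lme4 — profiled
deviance on sparse incidence matrices is exactly its algorithm, and
variance components are bounded at zero by its parameterisation. The
package owns the model-specification layer (declarative term lists:
linear, natural spline, categorical, interaction, quadratic interaction),
the standardization and its metadata, the Wald inference, and the
serialisation of results.

**Standardization.** All numeric fixed-effect columns are scaled to mean 0,
SD 1 (denominator $n-1$) before fitting, so estimates are comparable effect
sizes; the means and SDs are stored in the fit and reused for prediction
grids. A tested equivariance identity (standardized estimate = raw
estimate × predictor SD) guards the bookkeeping.

**Splines.** Nonlinear temperature–mass responses use natural cubic splines
with 5 degrees of freedom: boundary knots at the observed range, interior
knots at equally spaced quantiles, linear beyond the boundary. The basis is
`splines::ns()`; correctness is established in the tests by refitting with
an independently coded truncated-power construction (identical fitted
values to 1e-8) and by numerically checking second derivatives beyond the
boundary knots (≤ 1e-6). Five degrees of freedom balances flexibility
against parsimony for a predictor observed over a ~15 °C range; the count
spline for hot events uses df = 3 because event counts take few distinct
values.

**Inference: Wald, not Satterthwaite.** Fixed-effect tests use Wald
statistics with a standard-normal reference and CIs of ±1.96 SE.
Satterthwaite denominator degrees of freedom are the common alternative for
Gaussian mixed models; at the scale these models are used (thousands of
groups, denominator df in the thousands) the t and normal references are
practically indistinguishable, and the normal reference keeps the Gaussian
and binomial paths symmetric. The choice is recorded here and in the fit
objects' documentation.

**Model roster.** The preset roster enumerates the analysis families per
stage and event type: ambient spline/linear models; ECE count models
(count + stage mean temperature + lay date + clutch size); binary-presence
variants; ECE × ambient-weather interactions; ECE × relative-lay-date
interactions, the rain variant adding a quadratic count interaction
(count² × relative lay date) to capture an accelerating decline; and
categorical-ECE recruitment models. Hot and cold counts never enter one
model together — they are strongly negatively collinear by construction —
and this is enforced by a roster test. Recruitment models pool high counts
into a single top category ("4+" by default) because few chicks experience
many events; the reference level is always zero events, so each coefficient
is a contrast against no exposure. Lay date can be added to recruitment
models by option, mirroring the fitted-both-ways design. Generalized
variance inflation factors (Fox–Monette determinant formula, reducing to
$1/(1-R^2)$ for single columns) are computed in-package — the contract
takes a design, not a fitted model — and are cross-checked against
`car::vif()` in the tests.

**Path analysis.** Lay date, stage temperature and ECE exposure are
correlated by season, so the total lay-date effect on mass is decomposed by
recursive least squares on standardized variables: each mediator regressed
on lay date (path $a$), the outcome regressed on lay date plus all
mediators (direct path and paths $b$), indirect effects $a \times b$, total
= direct + Σ indirect. With this layout the total equals the reduced-form
regression coefficient *exactly* (an algebraic identity of nested OLS), and
the package asserts that identity to 1e-8 on every fit rather than treating
it as an empirical result.

## 5. The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised,
and the estimators validated by parameter recovery, without access to a
restricted life-history dataset. Its defaults encode the emulated study
conditions and were chosen once, on realism grounds, before being used in
tests.

* **Weather.** Daily temperature = seasonal cosine (annual mean 9.7 °C,
  amplitude 6.6 °C, peak day 203 — a central-England-like regime) plus
  AR(1) noise with coefficient 0.7 and innovation SD 2.2 °C (stationary SD
  ≈ 3.1 °C, lag-1 autocorrelation matching temperate daily anomalies).
  Persistence matters: it creates realistic multi-day extreme runs, which
  the counting semantics must handle. Rainfall is an independent Bernoulli
  (p = 0.5) × gamma(0.7, scale 6.5 mm) process — intermittent, right-skewed
  daily totals. The generator's moments (mean, lag-1 autocorrelation,
  wet-day fraction and amounts) are verified against their configuration in
  the tests.
* **Breeding structure.** Each year contributes a fixed number of first
  clutches; lay dates are normal (mean day-of-year 115, SD 9, truncated to
  April–June) with an optional per-year trend to emulate advancing
  phenology; hatch follows lay by 19 days (laying plus incubation); clutch
  size is 1 + Poisson(7.6) (mean ≈ 8.6); mothers and nestboxes are drawn
  from finite pools sized for realistic reuse (~2.5 broods per mother, ~3
  per nestbox across years, never twice in one year).
* **Outcomes.** Chick mass is built from the *same* standardized predictors
  the models fit — the generator consumes exposure records computed by the
  production exposure code, never a private re-derivation — with
  configurable coefficients in latent SD units (defaults near published
  effect magnitudes for this system: rain-event effect −0.143, lay-date
  effect −0.223), random-intercept SDs (year 0.30, brood 0.45, mother 0.30,
  nestbox 0.15), residual SD 0.70, and a gram scale of 1.4 g per latent SD
  about an 18.5 g intercept, reproducing a realistic mass median and IQR.
  Recruitment is Bernoulli on a logit linear predictor with year and brood
  intercepts; the configured value is the *marginal* recruitment fraction
  (default 9.1%), converted to a conditional intercept with the standard
  logistic-normal mean approximation
  $E[\mathrm{logit}^{-1}(\mu + \sigma Z)] \approx
  \mathrm{logit}^{-1}(\mu / \sqrt{1 + c^2\sigma^2})$, $c = 16\sqrt3/(15\pi)$,
  so the simulated cohort fraction matches the configured rate in
  expectation.
* **Standardization agreement.** The generator standardizes predictors by
  their realized sample moments — the same convention the fitter uses — so
  generating and estimated coefficients live on the same scale, and
  recovered estimates can be mapped to latent SD units exactly through the
  configured gram scale.

**What the generator does not emulate.** Mechanistic growth, parental
provisioning behaviour, density dependence, spatial habitat structure,
observation error in dates, second clutches, and any dependence of clutch
size or phenology on weather. Passing recovery tests therefore demonstrate
that the estimators recover known effects under the stated stochastic
structure; they cannot certify behaviour under confounding mechanisms the
generator does not contain.

## 6. Validation design and problem sizes

The test suite validates each stage against an independent oracle
(group-and-average baselines to 1e-12, brute-force day loops for exposure,
truncated-power spline refits to 1e-8, auxiliary-regression and `car::vif`
checks, closed-form normal quantiles for calibration) and the estimators by
end-to-end recovery. The recovery scale — 50 replicates of 20 years × 50
broods (≈ 8,500 chicks per replicate) for the Gaussian model, 50 replicates
of 10 years × 40 broods for the categorical recruitment model, and a
20-replicate null-component run — was chosen so that Monte-Carlo error on
the mean recovered coefficient (≈ 0.002 SD units) is an order of magnitude
below the ±0.02 acceptance band while the whole suite stays comfortably
desk-scale. Checks on the recovered rain-event effect (mean within ±0.02 SD
of the generating −0.14, nominal 95% CI coverage ≥ 90%), on all generating
coefficients (bias < 0.03, coverage ≥ 85%), and on a deliberately absent
mother component (< 5% of total variance in ≥ 90% of replicates) run in the
acceptance test file. Dataset descriptor tolerances (median mass ±0.4 g,
recruitment ±0.03) are three times the year-level Monte-Carlo SD implied by
the generator's own variance configuration at that scale.

## 7. Numerical and degenerate-input behaviour

* Duplicate dates, negative rainfall, unparseable dates, orphan chicks and
  out-of-range recruitment are errors naming the offending row or id;
  missing hatch dates exclude the brood with a warning and a machine-readable
  exclusion list.
* A constant column cannot be standardized (error naming it); rank-deficient
  designs error naming the aliased columns; perfect collinearity in VIFs is
  reported as `Inf`, not an exception.
* Mixed-model non-convergence is flagged on the result (`converged`,
  `notes`), never thrown; suspected complete separation in logistic fits is
  flagged from inflated estimate/SE pairs.
* Degenerate threshold calibration (all deviations equal) returns that
  value for every cutoff; calibration requires at least 100 non-missing
  days.
* All stochastic routines take explicit seeds; the pipeline default seed is
  20240101, and identical seeds reproduce byte-identical outputs at every
  stage (a tested property).

## 8. Known limitations

Wald inference slightly understates uncertainty for variance-component-rich
Gaussian models at small group counts (where Satterthwaite df would be
small); the recruitment models assume independence of emigration and
fledging mass (recruitment underestimates true survival); the ECE
definition assumes the deviation distribution is stable over the
calibration span, so long-term variance trends fold into event frequencies;
and the brood-specific baseline variant recomputes temperature events only.
The command-line wrapper is a convenience layer; the package functions and
`run_pipeline()` are the supported interface.
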