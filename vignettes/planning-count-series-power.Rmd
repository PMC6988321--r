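---
title: "Planning precision and power for count time-series regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning precision and power for count time-series regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspower)
```

## The model and what drives precision

Time-series studies of short-term environmental effects regress a daily
count $Y_i$ on an exposure $x_i$ with a log link,

$$E(Y_i) = \exp(\alpha + \beta x_i + \boldsymbol\gamma \boldsymbol z_i),$$

where $\boldsymbol z_i$ collects confounder-control covariates — in practice
a natural cubic spline of date (seasonality and trend), day-of-week
indicators, and possibly weather or co-pollutant terms. Counts usually show
scale overdispersion: residual variance $\varphi$ times the mean
(quasi-Poisson), with $\varphi$ rarely far above 1 for cause-specific
mortality.

`tspower`'s core is a set of closed-form approximations to the standard
error of $\hat\beta$ that expose what actually matters at the design stage:

* crude Poisson: $1/(\sqrt{\Sigma Y}\, SD(x))$ — ignores covariates,
  understates the SE whenever exposure is seasonal
  (`se_poisson_crude()`);
* Poisson with covariates: $1/(\sqrt{\Sigma Y}\, SD(x|z))$
  (`se_poisson()`);
* quasi-Poisson: $\sqrt{\varphi}/(\sqrt{\Sigma Y}\, SD(x|z))$
  (`se_quasipoisson()`).

Here $SD(x|z)$ — the *usable* exposure SD — is the SD of the residuals of a
linear regression of $x$ on $\boldsymbol z$, equivalently
$SD(x)\sqrt{1 - R^2_{x|z}}$. The striking consequence: given the total
event count, the number of days is irrelevant. Ten days at 1,000
deaths/day and 1,000 days at 10 deaths/day predict the same precision
(robustness to confounding is of course another matter). The squared ratio
$\left(SD(x)/SD(x|z)\right)^2$ is the familiar variance inflation ratio
(`variance_inflation_ratio()`).

From any SE follow the planning quantities (`ci_width()`,
`power_approx()`, `smallest_detectable()`, `required_events()`,
`years_required()`), all based on the two-sided normal approximation:
$\text{power} \approx \Phi(|\beta_{H1}|/SE - z_{\alpha/2})$, smallest
detectable coefficient $(z_{\alpha/2} + z_{1-\text{power}})\,SE$ (about
$2.80\,SE$ at $\alpha = 0.05$, power 0.8), and required events
$\varphi\,[(z_{\alpha/2} + z_{1-\text{power}})/(|\beta_{H1}|\,SD(x|z))]^2$.
The $\varphi$ multiplier in the last formula is an extension obtained by
substituting the quasi-Poisson SE; with the default $\varphi = 1$ it is the
plain Poisson requirement.

### Multiple series

For $J$ independent series pooled in a two-stage analysis
(`meta_fixed()`, `meta_random()`), the fixed-effects SE is the
single-series formula applied to the pooled event count (`se_fe()`):
again only total events and usable SD matter. With between-series
heterogeneity — true coefficients spread with SD $\tau$, a fraction $I^2$
of total variance — three random-effects approximations are offered, in
decreasing order of input demands:

* $\sqrt{1/\sum_j (\tau^2 + SE_j^2)^{-1}}$ with per-series SEs
  (`se_re_full()`);
* $SE_{FE}/\sqrt{1 - I^2}$, assuming constant per-series SEs
  (`se_re_from_i2()`);
* $\tau/\sqrt{J}$ under extreme heterogeneity (`se_extreme_het()`) — the
  regime where only the number of series helps.

These are exactly consistent: with constant per-series SE $s$ and
$I^2 = \tau^2/(\tau^2 + s^2)$, the first two coincide at
$\sqrt{(\tau^2 + s^2)/J}$.

## Parameters that matter, and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | two-sided significance level | 0.05 | field convention; all tests two-sided |
| `target_power` | power for the smallest-detectable block | 0.8 | conventional planning power |
| `required_power` | power for the required-events block | 0.9 | the more demanding figure usually quoted for sample size |
| `dispersion` | overdispersion $\varphi$ | 1 | low dispersion is typical for non-infectious daily deaths; $\varphi < 1$ is accepted with a warning rather than refused |
| `spline_df_per_year` | seasonal control | 7 | the conventional df/year for daily mortality series |
| `per_increment` (CLI/profiling) | exposure increment of the coefficient | 1 | makes unit conversions (e.g. per 10 μg/m³) explicit, never implicit |

Coefficients and $\tau$ are on the log-RR scale throughout the library; any
percent presentation (×100) happens only where results are printed.

### Printed-z ("hand-arithmetic") mode

Planning numbers are often checked against hand calculations that use
2-decimal normal quantiles (1.96, 1.28, 0.84). Every planning function
takes `printed_z = TRUE` to reproduce such arithmetic; the default is
full-precision quantiles ($z_{0.025} = 1.959964$). In `plan_single()` the
printed mode additionally carries the 3-decimal-rounded SE into the CI,
power and smallest-detectable lines, because that is how a hand calculation
proceeds from a reported SE; `plan_multi()` keeps the unrounded pooled SE
downstream, since its detectable-effect line is conventionally derived from
the full-precision SE. Reports round SEs to 3 decimals and powers to whole
percent (`full_precision = TRUE` in `print()` disables this); returned
objects always hold full precision.

One caution on the $I^2$ correction: multipliers sometimes quoted for
"$I^2$ of 10, 25, 50, 75%" (0.5, 3, 15, 51% SE inflation) correspond to
treating those values as $I$ rather than $I^2$ — e.g.
$1/\sqrt{1-0.75^2} = 1.512$. `se_re_from_i2()` implements the definition
literally ($1/\sqrt{1-I^2}$, so $I^2 = 0.75$ doubles the SE); the sweep
table in `plan_multi()` makes the mapping explicit.

## Estimating the usable SD from data

`usable_sd()` residualises a candidate exposure series on the design the
final analysis would use: intercept, natural cubic spline of day number
(`time_spline_basis()`, total df = `round(df_per_year × span in years)`,
boundary knots at the first/last date, interior knots at equally spaced
quantiles of the observed dates), day-of-week indicators
(`dow_indicators()`, Monday reference — irrelevant to the residual SD but
fixed for reproducibility), and optional extra covariate columns.
Numerical conventions:

* **Denominator.** Raw and residual sums of squares share one denominator
  so that $SD(x|z) = SD(x)\sqrt{1-R^2}$ and the Pythagorean decomposition
  hold exactly. The default is residual df $n - p$ (the unbiased-$\sigma$
  convention); `denominator = "n-1"` is available. For series of several
  years the difference is negligible; note that under $n - p$ an
  *uninformative* added covariate can leave the residual SD unchanged or
  trivially higher.
* **Missing data** are handled by complete-case analysis with a count of
  dropped rows; no imputation.
* **Degeneracies** are errors, not silent results: rank-deficient designs
  (with the collinear columns named), $R^2 = 1$, too few complete cases.
* **Percentile convention.** The linear-threshold transform
  `threshold_exposure()` (e.g. "heat" as temperature above its 75th
  centile) uses linear interpolation between order statistics (type 7);
  the transform depends on this, so it is fixed and documented.
  `lagged_mean()` provides running lag means (e.g. a 3-day mean for heat),
  undefined for the first `max(lags)` days.

`profile_exposure()` wraps this for a CSV with ISO-8601 dates, reporting
the residual SD after each incremental covariate block (none →
spline+day-of-week → each extra column), the way planning assessments step
through adjustment sets.

## The synthetic validation engine

Because precision approximations deserve checking against what a real
analysis would report, `tspower` ships a generator and harness
(`sim_config()`, `simulate_series()`, `fit_series()`, `empirical_se()`,
`validate_approximations()`, `validate_multicity()`).

**What the generator emulates.** Exposure is an annual cosine plus Gaussian
noise, so its raw and usable SDs have closed forms
($SD(x)^2 = A^2/2 + \sigma^2$; $SD(x|z) \to \sigma$ once the spline absorbs
the seasonal part). Outcome seasonality enters as a cosine in the linear
predictor with coupling strength $\gamma$; varying $\gamma$ and $A$ spans
$R^2_{x|z}$ from 0 to the ~0.4 typical of strongly seasonal exposures such
as heat. Overdispersed counts are negative binomial with per-observation
size $\mu_i/(\varphi - 1)$, which gives $Var(Y_i) = \varphi\,\mu_i$
*exactly* — the first two moments that quasi-Poisson $\varphi$ describes —
and degenerates to Poisson at $\varphi = 1$. First-stage fits use
`stats::glm(family = quasipoisson)`: SEs scaled by the Pearson dispersion
$\hat\varphi = \sum r_i^2/(n-p)$.

**What it does not emulate** — and hence what passing validation does and
does not show: no residual autocorrelation, no distributed-lag or
non-linear exposure-response structure, no measurement error, no
day-of-week signal in the truth (the indicators in the fitted model are
pure adjustment), and confounding that the spline can fully absorb. The
validation therefore tests the approximators under a correctly specified
analysis; with real data the dominant uncertainty is in predicting the
inputs ($\Sigma Y$, $SD(x|z)$, $\varphi$, $\tau$) rather than in the
formulas.

**Seed protocol.** All randomness flows from one master seed: a series
uses `seed` for the exposure stream and `seed + 1` for the count stream;
replicate $r$ of `empirical_se()` runs at `seed + 2r`; multi-city series
$j$ at `seed + 1000 + 2j`, with the coefficient draws
$\beta_j \sim N(\beta, \tau^2)$ at `seed` itself. Every table is
bit-reproducible from its configuration.

**Problem sizes.** The shipped scenario grid
(`default_validation_grid()`) is 20 Poisson scenarios crossing series
length (1,000–3,650 days), event rate (5–50/day), confounder coupling and
exposure shape; on it the usable-SD approximator tracks the fitted SE with
mean absolute error well under 10%. The day-count-irrelevance check
compares Monte-Carlo SEs (500 replicates) of two designs with equal
expected events (1,000 days × 10/day vs 2,500 days × 4/day). The
multi-city check uses 50 series of 2 years at 30 events/day with
$\tau = 0.007$ — heterogeneity comparable to the per-series SE, the regime
where ignoring it understates the random-effects SE by ~30% while the
$\tau$-based form stays close. Because a single DerSimonian–Laird
$\hat\tau^2$ at $J = 50$ carries substantial sampling noise, accuracy
claims are evaluated against the reference averaged over several fixed-seed
ensembles. These sizes keep the full suite to well under a minute while
leaving Monte-Carlo error comfortably inside the asserted tolerances.

## Design choices where the design was open

* **Random-effects estimator.** The pooling machinery uses the
  DerSimonian–Laird moment estimator with truncation at zero — the
  closed-form standard, matching the closed-form spirit of the
  approximators; the implementation is cross-checked against
  `metafor::rma(method = "DL")` in the test suite. REML would be a
  reasonable later addition.
* **$I^2$ definition.** Higgins–Thompson, $\max(0, (Q - (J-1))/Q)$.
* **Series independence** is assumed throughout; no spatial correlation
  structure is offered.
* **Reference SE in validation tables.** The single-replicate
  Pearson-scaled model SE plays the role of the "actual" SE (what an
  analyst would report); `empirical_se()` provides the Monte-Carlo
  alternative where a distribution-free reference is wanted.
* **Planning vs estimation conventions.** `required_events()` returns a
  positive real; users round up. `power_approx(0, se)` returns
  $\alpha/2$ — the probability of rejecting in one direction under the
  null — rather than an error.

## Limitations

The approximations are asymptotic normal-theory results: they say nothing
about bias, and they inherit the usual caveats for very short series or
very low counts. Not covered, by design: one-sided tests, exact Poisson
power, distributed-lag and non-linear exposure-response models,
case-crossover designs, autocorrelated residuals, negative-binomial or
zero-inflated outcome families as *fitting* models (the negative binomial
appears only as the overdispersion generator), meta-regression, and
imputation of missing exposure. For planning under model families beyond
these, the approximations remain useful as first-order guides, with the
usable-SD input recomputed for the simplified linear surrogate of the
intended model (e.g. the running-mean exposure for a distributed-lag
cumulative effect, via `lagged_mean()`).

## A compact worked session

```{r example}
# single series: 3,888 expected deaths, usable SD 0.76 per 10 ug/m3
plan_single(3888, 0.76, sd_raw = 0.97, beta_h1 = 0.06,
            required_power = 0.9, events_per_year = 486,
            printed_z = TRUE)

# ten cities, 2.5-fold the events, fixed effects + heterogeneity sweep
plan_multi(10, 9720, 0.76)

# how accurate are the closed forms? two synthetic scenarios
rows <- validate_approximations(list(
  sim_config(n_days = 1000, baseline_rate = 10, seed = 1),
  sim_config(n_days = 3650, baseline_rate = 20,
             confounder_coupling = 0.3, seed = 2)))
validation_summary(rows)
```
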