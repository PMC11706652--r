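---
title: "Pooling temperature and year effects on fish reproductive phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling temperature and year effects on fish reproductive phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phenometa)
```

## The model

Each extracted effect is a Pearson correlation $r_i$ between an annual
predictor (a temperature index, or the calendar year itself) and an annual
reproductive date (day of year), observed over $n_i$ years. Correlations are
bounded and skewed, so each is transformed to Fisher's $Z$,

$$Z_i = \tfrac{1}{2}\left[\ln(1+r_i) - \ln(1-r_i)\right], \qquad
\operatorname{Var}(Z_i) = \frac{1}{n_i - 3},$$

which is approximately normal with a variance that depends only on the
series length. The common-effect (fixed-effect) pooled estimate for a group
of effects is the inverse-variance weighted mean

$$\bar{Z} = \frac{\sum_i Z_i W_i}{\sum_i W_i}, \qquad W_i = n_i - 3,
\qquad \operatorname{SE}(\bar{Z}) = \Big(\sum_i W_i\Big)^{-1/2},$$

with a normal-quantile confidence interval; a group effect is called
significant when that interval excludes zero. The model assumes all effects
in a group estimate one common underlying correlation — field data are
certainly more heterogeneous than that, which is why the package reports
both the interval and the per-group effect count, and why the conservative
dataset (below) exists as a robustness check.

All correlations are first placed on one sign convention: $r$ relates the
predictor to the day-of-year, so $r < 0$ means *earlier* reproduction as the
predictor increases and $r > 0$ means *later*. Rows extracted from studies
that reported the opposite axis are flagged with
`direction = "earlier_with_increase"` and flipped by `align_sign()`.

Effects with $|r| \ge 1$ or fewer than 4 years are rejected at ingestion
rather than clamped: a perfect correlation over several field seasons is an
extraction error, and clamping would silently hand it an arbitrary weight.

## Inclusive and conservative datasets

Publications often contribute several effects (multiple species, multiple
rivers). Two dependency rules are applied:

* **Inclusive** — keep everything except alternative measurements of the
  *same fish observations* (e.g. the same population's spawning date
  correlated with both air and water temperature). One row per duplicate
  group is kept, preferring water-temperature predictors over air and
  peak-spawning metrics over onset, ties to the first row listed; every
  exclusion is logged in the dataset manifest. Duplicates are keyed on
  (study, species, population, predictor), so the effect table carries an
  optional `population` column; when it is absent each row is treated as an
  independent population and nothing is deduplicated.
* **Conservative** — additionally keep a single randomly chosen effect per
  (study, species) pair. The draw iterates groups in sorted key order from
  one seeded stream, with candidates sorted by effect id, so the subsample
  is reproducible given the seed and invariant to row order. Different seeds
  give different subsamples, and pooled values from conservative runs should
  be read as one random realization — sign flips relative to the inclusive
  pool are possible in small groups.

## Publication-bias diagnostics

`egger_test()` regresses each $Z_i$ on its standard error with weights
$W_i$, treating the sampling variances as known (coefficient covariance
$(X^\top W X)^{-1}$, no residual dispersion factor), and refers
coefficient/SE to a standard normal. This is the modern meta-regression form
of Egger's test and is what a fixed-effect meta-regression in standard
meta-analysis software produces; the test suite verifies exact agreement
with an independent normal-equations oracle and with the metafor package's
fixed-effect regression test. The classical variant — OLS of the
standardized effect on precision, asymmetry read from the intercept — is
available via `variant = "precision_regression"`. Because that variant
estimates its SE from residuals, it (unlike the default) collapses to a
zero p-value on a noiseless linear funnel; the two variants agree on the
asymmetry coefficient itself.

Groups with fewer than three effects are not tested, and a group whose
variances are all equal is rejected as a singular design rather than
silently producing a coefficient.

## Interannual variability of spawning dates

For populations with at least four annual dates, the variability measure is
the *range*: latest minus earliest day of year over all years observed
(`n_years` counts observed years, not the calendar span). Autumn spawners
near the calendar boundary are unwrapped first — if a series spans more than
half a year, dates below day 183 are shifted by +365 — because a population
spawning in late December and early January would otherwise show a
\>350-day range.

Ranges from all populations (both seasons pooled) pass through a two-sided
Tukey fence: points beyond $Q_3 + 1.5\,\mathrm{IQR}$ or below
$Q_1 - 1.5\,\mathrm{IQR}$ are removed before modelling. Quartiles use linear
interpolation between order statistics (R's default type 7); on edge cases a
different quantile convention could move a borderline point across the
fence, so the type is a visible argument.

The screened ranges are modelled as

$$\text{range} \sim \text{duration} + \text{season}
\;(+\; \text{duration} \times \text{season}),$$

by ordinary least squares. The interaction is fitted first and dropped when
its p-value exceeds `alpha` (default 0.05, exposed as configuration); when a
saturated fit leaves the test undefined the interaction is likewise dropped,
there being no evidence for it. Per-season estimated marginal means are
evaluated at the grand-mean duration of the records entering the final
model, using the emmeans package; the tests check them against a hand-rolled
least-squares oracle. Migration records are excluded from this analysis —
migration is a distinct process from spawning — and the raw per-season mean
ranges are recoverable from the returned records for readers who want
unadjusted summaries alongside the EMMs.

## The synthetic study generator

`sim_scenario()` + `simulate_effect_table()` / `simulate_range_data()`
generate data with the statistical structure the analysis assumes:

* Each population-year is
  $DOY_t = \mu + \beta (x_t - \bar x) + trend \cdot t + \varepsilon_t$ with
  $\varepsilon_t \sim N(0, \sigma^2)$. Temperature predictors are standard
  normal anomalies — only the correlation structure matters downstream, not
  absolute degrees; year predictors are the calendar sequence, whose spread
  grows with series length, and the slope is rescaled accordingly. The slope
  for a target correlation $\rho$ is
  $\beta = \rho\sigma / (\sigma_x\sqrt{1-\rho^2})$ (`rho_to_effect()`).
* The default scenario mirrors a typical published temperature literature:
  28 spring-spawning, 8 autumn-spawning and 46 autumn-migration effects with
  group correlations of about $-0.65$, $+0.57$ and $-0.29$, studies of 5–40
  years bundled into publications of 1–4 effects across one or two species;
  for calendar-year predictors the canonical counts are 52/14/79 with
  weaker correlations (about $-0.3$ to $-0.2$). Range data default to 40
  spring and 24 autumn populations of 5–60 years with interannual date SDs
  of 8.5 and 5.3 days — values that put expected ranges near 30 and 20 days
  at typical durations, the magnitudes reported for temperate fishes.
* A `direction_flip_prob` fraction of rows is reported on the flipped date
  axis so the sign-alignment step is exercised, and `asymmetry_knob`
  injects small-study bias by truncation: short series are re-simulated
  until $|r|$ clears the knob in the direction of the true effect,
  mimicking selective reporting rather than shifting effects additively.
* One master seed spawns per-component substreams, so effect tables and
  range data can be regenerated independently yet reproduce jointly, and
  generators restore the caller's RNG state.

What the generator does *not* emulate: between-study heterogeneity in the
true correlation (all effects in a group share one $\rho$), autocorrelated
or trending climate series, measurement differences among phenology metrics,
and the long (up to 111-year) durations of a few real datasets. Passing
tests therefore demonstrate that the pipeline's arithmetic and calibration
are correct under the common-effect model, not that real literatures satisfy
that model. One visible consequence: synthetic confidence intervals are
narrower than those from heterogeneous field data at the same effect counts,
and the range generator's season-specific noise makes the
duration-by-season interaction genuinely nonzero (expected range grows like
$\sigma \cdot E[\text{range of } n \text{ standard normals}]$), so the
interaction screen sometimes retains it — the ANCOVA handles both outcomes.

## Numerical choices

* Fisher's transform is computed from its logarithmic definition and the
  back-transform as $\tanh$; the round-trip is exact to $10^{-12}$ over the
  full usable range.
* Pooled CIs use normal quantiles (1.96 at 95%), the convention for
  fixed-effect inverse-variance pooling; t-based intervals would be slightly
  wider at small $k$. Reported `±` values are CI half-widths, and the SE is
  emitted alongside to disambiguate.
* Pooling a single effect is allowed but warned about; its interval is just
  that effect's own sampling interval.
* No heterogeneity statistic is computed by default; the fixed-effect model
  is the analysis model throughout, including in the Egger regression
  weights.
* Test problem sizes: $10^4$ series for the variance validation, 2000
  replicate meta-analyses for CI coverage, 1000 null funnels for the Egger
  type-I rate, 100 biased scenarios for power — sizes at which the binomial
  Monte Carlo error is comfortably inside each asserted band.

## Limitations

Fixed-effect pooling understates uncertainty when true effects vary across
studies; random-effects variance components are deliberately out of scope.
The dependency rules operate within publications only — the same population
published twice in different papers is not detected. Season and process
labels are taken from the data as asserted by the original study authors,
never inferred from the dates themselves. Trim-and-fill, selection models
and rank-based bias tests are not provided; the Egger regression is a
diagnostic, not a correction.
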