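# phenometa

Fixed-effect meta-analysis of how annual temperature and calendar year relate
to the reproductive timing of temperate freshwater fishes.

## The problem

Temperate freshwater fishes spawn seasonally, in spring or autumn, and the
calendar date of spawning (or of the pre-spawning migration) varies from year
to year with environmental cues such as water temperature. Individual field
studies report this as a correlation between an annual predictor — a
temperature index or simply the year — and an annual phenology date. Each
study covers one or a few populations over a handful of years; synthesizing
them requires putting heterogeneous correlations on a common scale, weighting
them by their information content, handling within-study dependency, and
checking for publication bias.

`phenometa` implements that synthesis for anyone working with tables of
(correlation, years-of-data) effect sizes in reproductive phenology:

* **Effect transformation.** Each correlation *r* from *n* years of data is
  transformed to Fisher's *Z*:

  *Z* = ½ [ln(1 + *r*) − ln(1 − *r*)],  Var(*Z*) = 1 / (*n* − 3)

  with inverse-variance weight *W* = *n* − 3. Signs follow a common
  convention: negative = earlier dates as the predictor increases.
* **Pooling.** Groups of effects (spring-spawning, autumn-spawning, autumn
  migration; per predictor; optionally split lentic/lotic) are combined with
  the common-effect weighted mean *Z̄* = Σ*Z*ᵢ*W*ᵢ / Σ*W*ᵢ, SE = (Σ*W*ᵢ)^−½,
  and a normal-quantile 95% CI; an effect is significant when the CI excludes
  zero.
* **Dependency handling.** An *inclusive* dataset keeps all effects except
  re-measurements of the same fish observations; a *conservative* dataset
  keeps one randomly selected effect per species per publication
  (seeded, reproducible).
* **Publication-bias diagnostics.** Egger-type regression of *Z*ᵢ on its
  standard error (fixed-effect weighted meta-regression; a classical
  precision-regression variant is available) per analysis group.
* **Phenological variability.** Per-population interannual spawning-date
  ranges (max − min day-of-year, with circular unwrapping for winter-boundary
  spawners), Tukey-fence outlier screening, and an ANCOVA of range on study
  duration and season with estimated marginal means at the grand-mean
  duration.
* **Synthetic studies.** A seeded generator of effect tables and date series
  with known true correlations, trends, noise levels and optional
  small-study bias, so the whole pipeline is testable end to end.

## Worked example

```r
library(phenometa)

scn     <- sim_scenario(seed = 2024)         # canonical synthetic literature
effects <- simulate_effect_table(scn)        # raw extracted rows
ranges  <- simulate_range_data(scn)          # per-population date ranges
res <- run_full_analysis(effects, ranges = ranges,
                         config = run_config(seed = 2024))

res$pooled[res$pooled$dataset == "inclusive",
           c("season", "process", "k", "z_bar", "ci_halfwidth", "r_bar",
             "significant")]
#>   season   process  k  z_bar ci_halfwidth  r_bar significant
#> 1 autumn migration 46 -0.320       0.0634 -0.310        TRUE
#> 2 autumn  spawning  8  0.778       0.1545  0.652        TRUE
#> 3 spring  spawning 28 -0.812       0.0829 -0.671        TRUE

res$ancova
#> ANCOVA: date range ~ duration + season (n = 64)
#>   interaction dropped (p = 0.140 > 0.05)
#>   R^2 = 0.616, F(2, 61) = 48.91, p = 2.12e-13
#>   EMMs at duration = 33.6 years:
#>     autumn: 21.4 +/- 1.0 days
#>     spring: 32.4 +/- 0.8 days
#>   season contrast p = 1.44e-11
```

Read the pooled table as: spring spawners shift **earlier** with warmer
years (pooled Fisher's *Z* = −0.81, i.e. a pooled correlation of −0.67, CI
half-width 0.08, CI excludes zero), autumn spawners shift **later**
(*Z̄* = +0.78), and the autumn spawning migration shifts slightly earlier
(*Z̄* = −0.32). The ANCOVA says that, at a common 33.6-year study duration,
spring populations span about 32 days of interannual spawning-date variation
versus about 21 days for autumn populations, with the duration slope and the
season contrast both significant.

Real data enter the same path as CSV files (`read_effects_csv()`,
`read_series_csv()`; see their help pages for the column schema), and
`run_full_analysis(..., out_dir = "out")` writes tidy CSVs, a plain-text
summary and a JSON manifest. A thin command-line wrapper with
`pool`, `egger`, `range-ancova`, `simulate` and `run-all` subcommands is
installed at `inst/scripts/phenometa`.

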