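# smeedfit

Road-safety epidemiology asks when a motorizing country passes through its
worst years of road-traffic mortality. `smeedfit` implements the modified
Smeed model of that process: the population-based death rate first rises
with motorization and later falls as safety management catches up,

    D/P = a · (N/P) · exp(−b · N/P)

where `D` is annual road-traffic deaths, `N` registered motor vehicles and
`P` population. Throughout the package `D/P` is measured in deaths per
100,000 persons and `N/P = x` in vehicles per person. Substituting
`Y = ln(D/P) − ln(N/P)` turns the curve into the linear model
`Y = β₀ + β₁·x + ε` with `β₀ = ln a` and `β₁ = −b`, which is fitted by
ordinary least squares. Two closed-form quantities summarise a fitted
country:

- **Predicted maximum mortality (PMM)** `= a/(e·b)` — the height of the
  mortality peak, in deaths per 100,000;
- **Peak motorization** `= 1/b` — the motorization level at which the peak
  occurs. A lower value means the country got mortality under control
  earlier in its motorization; mapping `1/b` back onto the observed
  motorization trajectory dates the peak in calendar time.

The package is aimed at injury epidemiologists and transport-safety
researchers who fit this model to national panel data (country, year,
deaths, vehicles, population) — including data-quality questions such as
whether a police-reported series with a 7-day fatality definition (counts
scaled by 1.08 to the international 30-day convention) tells the same
story as health-registration data. The fitting pipeline applies the
standard influence diagnostics for this literature: observations with
|externally studentized residual| > 3 or Cook's distance > 1 are excluded
and the model refitted. A seeded synthetic-panel generator reproduces the
model's statistical structure for parameter-recovery and
outlier-detection experiments.

## Worked example

Simulate a country observed 1970–2013 whose motorization grows
logistically from 0.01 to 0.40 vehicles per person, with one contaminated
year, then run the full pipeline:

```r
library(smeedfit)

cfg <- generator_config(seed = 42, country = "Synthetica",
                        outliers = data.frame(year = 1995, shift_sd = 10))
gen <- generate_series(cfg)
pts <- transform_series(gen$series)   # (x, Y) regression points
res <- fit_with_exclusion(pts)        # fit, diagnose, exclude, refit
res
#> Smeed fit with outlier exclusion: n_used = 43, excluded = 1
#>   - 1995: |studentized residual| = 8.23 > 3.0
#>   R^2 = 0.965, F = 1125.762, p <0.001
#> Modified Smeed parameters
#>   a = 289.0073  b = 6.0363   (beta0 = 5.6665, beta1 = -6.0363)
#>   peak: 17.6 deaths/100,000 at 0.166 vehicles/person

comparison_table(list(summarize_peak(gen$series, res)))
#> Peak-analysis comparison (ranked by peak motorization)
#>      country source_note  pmm peak_x peak_period note below_reference_min
#> 1 Synthetica   synthetic 17.6  0.166   1989-1990                    FALSE
#> PMM range: 17.6-17.6 deaths/100,000; peak motorization range: 0.166-0.166
```

The injected 1995 contamination is flagged and removed; the refit
recovers the generating curve (true a = 273.42, b = 5.742, peak 17.5
deaths/100,000 at 0.174 vehicles per person) within sampling error. The
peak-period label `1989-1990` is the pair of observed years whose
motorization brackets the fitted peak level 0.166.

`table_fixtures()` ships the published 15-row cross-country worked
example (China fitted twice, from health-registration and police data,
plus 13 OECD countries) as printed coefficients with their derived peak
quantities, so the closed-form identities `a = exp(β₀)`, `PMM = a/(e·b)`
and `peak_x = 1/b` can be checked directly.

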