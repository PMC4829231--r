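---
title: "Methods: the modified Smeed model, its fitting pipeline and the synthetic-data design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the modified Smeed model, its fitting pipeline and the synthetic-data design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smeedfit)
```

## The model

The modified Smeed equation describes how a country's road-traffic
mortality evolves as it motorizes:

$$\frac{D}{P} = a \cdot \frac{N}{P} \cdot e^{-b\,N/P},$$

with $D$ annual road-traffic deaths, $N$ registered motor vehicles and
$P$ population. At low motorization ($N/P \to 0$) the exponential factor
is close to 1 and mortality grows roughly linearly with motorization, at
rate $a$. As motorization rises, safety responses (road design, vehicle
standards, enforcement, trauma care) increasingly dominate and the
exponential decay wins: the curve is unimodal for $b > 0$, rising on
$(0, 1/b)$ and falling beyond. Its maximum — the *predicted maximum
mortality*, $\mathrm{PMM} = a/(e\,b)$ — is attained at motorization
$1/b$. Countries whose $1/b$ is small turned the corner early; a fitted
$1/b$ far below every comparable country's is a red flag for the data
source rather than evidence of exceptional management, which is what
makes the model useful for auditing conflicting national statistics.

**Units are fixed package-wide**: $D/P$ in deaths per 100,000 persons
and $N/P$ in vehicles per person. This convention is forced by internal
consistency of the published worked example the package ships as
`table_fixtures()` (e.g. $a = 273.42$, $b = 5.742$ gives
$\mathrm{PMM} = 17.5$ deaths/100,000 at $N/P = 0.174$), and every
function in the package assumes it.

## Assumptions

* Writing $Y = \ln(D/P) - \ln(N/P)$ and $x = N/P$ linearizes the model
  to $Y = \beta_0 + \beta_1 x + \varepsilon$ with $\beta_0 = \ln a$,
  $\beta_1 = -b$. The error $\varepsilon$ is assumed Gaussian on this
  log scale — multiplicative (lognormal) noise on mortality — which is
  the scale on which the model is fitted by ordinary least squares.
* Observations are treated as exchangeable points, not a time series:
  no autocorrelation structure is modelled, and gap years (panels
  observed e.g. in 1970, 1980, then annually) are unremarkable.
* Records with zero deaths or zero vehicles have no defined logarithm;
  they are excluded from the transformation with a message rather than
  an error, since occasional structural zeros occur in early-period
  national data.
* Deaths recorded under a 7-day fatality definition are converted to the
  30-day convention by the factor 1.08 before any rate is computed. The
  adjusted counts are *not* rounded back to integers: the factor is a
  statistical correction, not a recount.

## Fitting and influence diagnostics

`fit_ols()` estimates $(\beta_0, \beta_1)$ by least squares and reports
$R^2$ and the overall $F$ statistic on $(1, n-2)$ degrees of freedom.
For a simple regression these are redundant —
$F = R^2 (n-2)/(1-R^2)$ — and the test suite verifies that identity on
every fit.

`fit_with_exclusion()` implements the conventional outlier rule for
this literature: an observation is an outlier when its
|studentized residual| exceeds 3.0 or its Cook's distance exceeds 1.0.
Three genuinely open choices were settled as follows:

* **Externally studentized residuals** (leave-one-out scaling) are used
  for the call, because the $|t| > 3$ convention refers to the external
  variant; the internal variant is also computed and exposed in the
  diagnostics table so the sensitivity of a call can be inspected.
* **Exclusion is single-pass**: fit, diagnose, remove all flagged
  points, refit once. This matches how a small set of named outliers is
  typically removed in applied work. An iterative mode
  (`iterate = TRUE`) repeats the cycle to stability but is off by
  default.
* **Thresholds are strict inequalities**: a point with
  $|t| = 3.0$ exactly is not flagged.

Degenerate inputs are refused early: fewer than 3 points (4 for the
exclusion pipeline, so a removal cannot leave an unidentifiable fit),
or all-identical $x$. If exclusion would leave fewer than 3 points the
unexcluded fit is returned with a warning instead. With $n \le 3$ the
diagnostics are computed but flagged as unstable. Displayed $p$-values
below 0.001 print as `<0.001`; full precision is stored.

## Dating the mortality peak

The fitted peak is a motorization level, $1/b$, not a date.
`locate_peak_year()` dates it by intersecting $1/b$ with the *observed*
motorization trajectory:

* below the observed range → `"Before <first year>"` (the country was
  already past its peak when records begin);
* above it → `"After <last year>"`;
* within relative tolerance $10^{-3}$ of an observed year's
  motorization → that year (the tolerance mirrors the 3-decimal
  precision at which peak motorization is conventionally reported);
* otherwise the two observed years bracketing the first crossing,
  labelled `"1993-1994"` style. With gap years the label spans the gap
  (e.g. `"1980-1990"`), which is exactly what a decade-wide bracket in
  a sparse panel means.

Real trajectories are occasionally non-monotone (vehicle re-registration
reforms, wars); the first crossing is used and a warning raised. An
alternative definition — the year of maximum *observed* mortality — was
considered and rejected as the default because it ignores the fitted
curve entirely and is noisy at typical sample sizes; the observed
trajectory is still available to users who want it. Because only the
$x$-trajectory enters, the label is invariant to rescaling deaths, and
the test suite checks that property directly.

`comparison_table()` ranks countries by peak motorization and, given a
designated reference set, flags entries whose peak falls below the
reference minimum — the operational form of the "suspiciously early
peak" argument sketched above.

## The synthetic-data generator

`generate_series()` produces panels with *exactly* the structure the
model assumes, so that every pipeline stage is testable without any
national dataset: motorization follows a deterministic trajectory,
$Y = \beta_0 + \beta_1 x + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2)$ i.i.d., and deaths/vehicles are
reconstructed from a chosen population. Defaults, chosen once:

* **44 annual observations, 1970–2013** — the span of the longest
  published series the model is applied to;
* **truth $(\beta_0, \beta_1) = (\ln 273.42, -5.742)$** — the
  China-health row of the shipped fixture table, a mid-range curve
  (peak 17.5 deaths/100,000 at 0.174 vehicles/person);
* **logistic trajectory from 0.01 to 0.40 vehicles per person** —
  slow–fast–slow growth is the shape of real motorization curves, and
  the range carries the series through the default curve's peak; an
  exponential option covers low-motorization regimes that never reach
  the peak;
* **$\sigma = 0.15$ on the $Y$ scale** — published fits of this model
  report $R^2$ between 0.83 and 0.98 but no residual variances; 0.15
  on the log scale (≈ ±15% multiplicative noise in mortality)
  reproduces that goodness-of-fit range at the default design and is
  therefore a plausible, not data-derived, value;
* **seeds are mandatory** — there is no silent global-RNG path, and
  every stochastic test enumerates its seeds.

Outliers are injected as shifts of stated size *in units of* $\sigma$
on the $Y$ scale. A panel generated under the 7-day definition stores
deaths divided by 1.08, so the data-io adjustment reconstructs the
30-day counts bit-for-bit.

What the generator does **not** emulate: underreporting that trends
over time, mid-series definition changes, autocorrelated errors,
population-structure effects, or measurement error in vehicle counts.
Passing the simulation tests therefore shows the pipeline is correct
*under the model's own assumptions*; it cannot certify behaviour on
real national data, where those violations are precisely what is at
issue.

## Simulation designs in the test suite

The suite runs four designed experiments, sized to be decisive yet
quick (each is seconds on one CPU):

* **Estimator equivalence**: 200 random instances, $n \in [3, 50]$,
  compared against longhand normal-equations arithmetic at absolute
  tolerance $10^{-10}$; the $F$–$R^2$ identity at relative $10^{-6}$.
* **Parameter recovery**: 500 replicates at the generator defaults
  ($n = 44$, $\sigma = 0.15$); mean bias of $\hat b$ within $\pm 0.05$
  and 95%-interval coverage for $\beta_1$ within $[0.92, 0.98]$.
* **Outlier pipeline**: 200 replicates with one $10\sigma$ contaminated
  year at a random position; the pipeline must remove exactly that year
  in at least 95% of replicates, and the refit must land closer to the
  fit on the matching uncontaminated panel than the contaminated fit
  does in at least 90%. The uncontaminated fit is the reference because
  it is what exclusion can at best recover; distance to the generating
  constant is not discriminating when the contaminant sits near the
  design centroid and barely tilts the slope.
* **Peak labelling**: 100 random monotone trajectories, with the label
  checked against direct endpoint comparison in every case.

Externally studentized residuals are validated against literal
leave-one-out refits, and leverage and Cook's distance against their
longhand formulas — the diagnostics never only agree with themselves.

## Known limitations

* The model requires a rise-then-fall mortality history; for a series
  still rising, $1/b$ extrapolates beyond the data (`"After <last
  year>"` labels it honestly, but the estimate is weak), and a series
  with no interior peak at all fits with $b \le 0$, for which peak
  quantities are deliberately undefined rather than coerced.
* OLS on the log scale downweights nothing: a single aberrant year can
  move the fit materially, which is why the exclusion rule is part of
  the standard pipeline rather than an afterthought.
* The coefficient table shipped in `table_fixtures()` is a printed
  worked example (3-decimal coefficients); quantities recomputed from
  it inherit that rounding, which matters at the second decimal of
  $a = e^{\beta_0}$.
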