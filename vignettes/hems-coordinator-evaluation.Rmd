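---
title: "Evaluating regional HEMS coordination: methods and design notes"
author: "hemseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating regional HEMS coordination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The evaluation problem

When a health system inserts a new link into an emergency dispatch chain —
here, a regional coordinator who alarms helicopter emergency medical
service (HEMS) crews instead of each local dispatch centre doing so — the
first question is whether the extra link delays the response. Randomising
such an organisational change is not possible, so the strongest available
design is quasi-experimental: an interrupted time series (ITS) on the
outcome, with a before/after comparison of how missions distribute
geographically between bases and of who the patients are.

`hemseval` packages that evaluation methodology so it can be exercised,
tested and reused without access to the operational registries the original
analysis drew on (such data are person-identifiable and not public). A
synthetic mission generator reproduces the statistical structure the
analysis assumes, and every analysis stage is a tested function.

## The segmented ITS model

Mission response times (alarm to arrival on scene, decimal minutes) are
aggregated into monthly means. The monthly mean at 0-based month index $t$
is modelled as

$$f(t) = \beta_0 + \beta_1 t + \beta_2\,u(t - t_{pi}) +
\beta_3 (t - t_{pi})\,u(t - t_{pi}) + \beta_4 I_{\text{winter}}(t) +
\varepsilon(t),$$

where $u$ is the unit step, $t_{pi}$ is the index of the intervention
month, $\beta_2$ is the immediate level change, $\beta_3$ the slope change,
$\beta_4$ the winter (October–March) elevation, and $\varepsilon$ a
stationary error process, by default first-order moving average (MA(1)) to
absorb month-to-month autocorrelation. Hypothesis tests on $\beta_2$ and
$\beta_3$ answer the level-change and trend-change questions.

Coding choices that the model equation does not pin down:

* **Month index.** $t = 0$ is the first study month; $t_{pi}$ equals the
  number of pre months (default 24, i.e. a January-2019 intervention for a
  January-2017 start).
* **Intervention month.** The intervention month itself is excluded (the
  change took effect mid-month); consequently the first *included* post
  month carries step 1 and ramp 1.
* **Winter indicator.** 1 for October through March inclusive.
* **Outlier months.** A month whose mean lies more than `z_threshold`
  (default 3) SDs from the mean of the other non-intervention months is
  excluded. The z-score is computed leave-one-out — the candidate month is
  excluded from the mean and SD it is tested against — because with only
  ~35 points a single extreme month inflates the pooled SD enough to mask
  itself. The threshold is configurable; the default study window then
  yields 24 included pre points and 10-11 post points depending on whether
  an outlier occurs.

### Estimation: why REML rather than plain ML

The error structures offered (`white`, `ma1`, `ar1`, `sma12` — seasonal MA
at lag 12) all have closed-form stationary correlation matrices with a
single parameter in $(-1, 1)$. `fit_its()` profiles $\beta$ and the error
variance out analytically and maximises the *restricted* likelihood of the
correlation parameter by exact one-dimensional search (tolerance `1e-8`),
so there is no iterative convergence to fail.

Restricted maximum likelihood is used deliberately. With ~34 monthly
observations and 5 mean parameters, plain ML underestimates the error
variance by roughly the factor $(n-p)/n$, and with the correlation
parameter estimated as well, Wald tests on $\beta_2$/$\beta_3$ built on
ML variances are anticonservative at this sample size. REML removes the
variance bias; the shipped simulations (500 null series, 200 recovery
series at the study's problem size — see `scripts/acceptance.R` and the
test suite) verify an empirical test size within $[0.01, 0.10]$ at
nominal 0.05 and CI coverage for $\beta_2$ within $[0.90, 0.99]$. Tests
use a $t$ reference with $n - 5$ degrees of freedom, matching standard
generalised-least-squares practice.

Excluded months are *gaps, not deletions*: correlations are evaluated at
true calendar lags, so two months separated by an excluded month are lag-2
neighbours (uncorrelated under MA(1)), not artificially adjacent.

### Error-model selection and fit statistics

`select_error_model()` fits each candidate and keeps the fit minimising
AICc $= \mathrm{AIC} + 2k(k+1)/(n-k-1)$, with $k$ counting mean,
correlation and variance parameters. Ties go to the model with fewer
parameters, then to candidate order. Because the mean structure is
identical across candidates, restricted likelihoods are directly
comparable. The candidate set is a documented default, not a
reconstruction of any particular historical analysis. $R^2$ is the
ordinary coefficient of determination of the regression mean against the
observed monthly means — it deliberately excludes the correlation
structure, and is labelled as such in outputs.

The counterfactual trajectory is $\beta_0 + \beta_1 t + \beta_4
I_{\text{winter}}(t)$: the pre trend extrapolated with seasonality, so that
(fitted − counterfactual) at post month $m$ is exactly
$\beta_2 + \beta_3(m - t_{pi})$.

## Service areas by convex hulls

For each base and period, mission GPS positions are reduced to a convex
hull after discarding the farthest 5% of missions (outlying long-range
missions otherwise dominate the hull):

* **Distance filter.** Geodesic distances from the base (WGS84 ellipsoid,
  via `geosphere`) are cut at the 95th percentile, defined by linear
  interpolation between order statistics; ties at the cutoff are retained.
  Note that re-applying the filter to its own output removes a few more
  points (the percentile of the retained subset is smaller) — the filter
  is monotone but not exactly idempotent, a direct consequence of the
  interpolated percentile definition.
* **Hull construction.** Points are projected into an azimuthal
  equidistant plane centred on the base, the planar hull is taken
  (`grDevices::chull`), and vertices are mapped back. At the ~300 km scale
  of a HEMS service area the discrepancy against a true geodesic hull is
  negligible; hull membership of *near-collinear* vertices is inherently
  projection-dependent at the metre scale.
* **Area.** The ring is projected with a Lambert azimuthal equal-area
  projection on the authalic sphere of the WGS84 ellipsoid, centred on the
  ring's mean position, and the planar shoelace formula is applied.
  Equal-area projection makes the km² value independent of hemisphere and
  starting vertex; the test suite cross-checks against an independent
  ellipsoidal area computation (agreement within 0.2%).
* **Comparison.** Median and IQR of mission distances are computed on
  *all* map-eligible missions (the hull uses the filtered subset), and the
  pre/post median difference carries a Mann–Whitney p-value and a
  Hodges–Lehmann 95% CI. Percent area change is computed from unrounded
  areas and rounded to 1 decimal only at render time.

## Descriptive battery

Pre/post comparisons follow the usual scale-appropriate choices:
chi-square without continuity correction for proportions (sex, severe
cases, mission distribution, threshold and scramble rates), Mann–Whitney
for skewed quantities (age, distances), Welch's t for NACA means (a pooled
Student variant is available). The Hodges–Lehmann estimate is the median
of all pairwise between-group differences; its CI inverts the
Mann–Whitney test via order statistics of the pairwise differences, exact
(`qwilcox`) up to 10,000 pairs and normal-approximated beyond. The 45-min
threshold ("within 45 minutes") is read as inclusive. Significance is
reported at 0.05 with no multiplicity adjustment, matching field practice
for descriptive tables; `p.adjust` can be applied downstream by users who
want it.

In-flight scrambles — alarms accepted while already airborne — are
operationalised as alarm-to-takeoff strictly under 2 minutes; exactly 2
minutes is not a scramble.

## The synthetic mission generator

`generate_missions()` emulates a three-base regional registry extract:

* **Volumes.** Poisson counts per base-month; default rates 46 / 28 / 13.5
  eligible missions per month for the three bases, i.e. ~87 regional
  missions/month and ~3,100 over the 36-month window, matching the
  published per-base mission distribution.
* **Response times.** Monthly mean follows the segmented model above
  (defaults: $\beta_0 = 29.9$, $\beta_1 = 0.05$ — chosen so the pre-period
  mean is ~31 min, the published magnitude, since no pre-slope is reported
  — $\beta_2 = \beta_3 = -0.13$, $\beta_4 = 1.1$, all in minutes); a
  shared regional MA(1) month shock ($\theta = 0.3$, innovation SD 1.5
  min) adds autocorrelation; missions add i.i.d. normal noise (SD 8 min)
  truncated below at the base start-up time, or at the drawn
  alarm-to-takeoff interval plus 0.1 min when that is longer, so
  alarm ≤ takeoff ≤ on-scene always holds. The truncation point is almost
  always far in the lower tail, so the induced mean shift is ~0.1–0.3 min.
* **Scrambles.** With probability 0.12 the alarm-to-takeoff interval is
  uniform on [0, 2) min; otherwise uniform on [start-up, start-up + 10].
* **Severity.** NACA scores are drawn from period-specific probability
  vectors with $P(\text{NACA} \ge 4)$ = 0.615 pre and 0.682 post; sex, age
  and ICD-10 chapter distributions follow the published patient table.
  ~1.7% of missions carry a second patient (contact a few minutes after
  the first), exercising the first-patient-contact collapse rule.
* **Locations.** Area-uniform over a geodesic disc (uniform bearing,
  radius $\propto \sqrt{U}$) of default radius 150 km, so the 95th
  percentile filter always has mass to act on.
* **Excludable records.** Cancelled, car, SAR, secondary, non-acute and
  no-contact records are generated at small configurable rates, and ~2.2%
  of eligible missions lack GPS (they stay in the response-time analysis
  and drop only from the maps, mirroring the two denominators of the
  published flow chart).
* **Determinism.** One RNG stream per dataset seeded from `config$seed`,
  with per-base sub-seeds; identical configurations and seeds are
  byte-identical on disk. CSV timestamps are whole-second (takeoff floored,
  on-scene ceiled, so rounding can never flip timeline order or the 2-min
  scramble threshold); the full-precision `response_min` column is the
  authoritative generated response time.

What the generator does *not* emulate — and hence what passing tests do
not establish about real registry data: response-time distributions are
truncated normal, not right-skewed as real ones are (the published
standard errors imply a mission-level SD near 18 min; a normal with that
SD and a 31-min mean would be implausible, so the default SD is 8 min and
the 45-min coverage of synthetic data runs a few points higher than the
published 88%); no flight physics (response time is drawn statistically,
not computed from distance and cruise speed); no weather, duty-time or
concurrency effects; no per-base differences in mean response time; and
mission locations are isotropic around bases rather than following
population and terrain.

## Validation problem sizes

The test suite characterises the ITS estimator with 200 replicate
36-month series for parameter recovery/coverage and 500 for test size
(these simulations exclude only the intervention month — no data-dependent
outlier trimming, which would slightly attenuate a true level change);
convex hulls are checked against an exhaustive $O(n^3)$ edge-test oracle
on 100 random point sets; the Hodges–Lehmann implementation against
brute-force pairwise medians up to $50 \times 50$; Mann–Whitney against
full enumeration at $4$ vs $4$; and the geodesic backend against the
numerically integrated WGS84 meridian arc. The end-to-end pipeline is
required to be byte-identical under a fixed seed.

## Worked pipeline

```{r pipeline}
library(hemseval)
cfg <- default_config(seed = 42)
res <- run_pipeline(cfg)
res$model        # segmented fit, selected error structure
res$report       # descriptive battery + service areas
plot_its(res$model)
write_report(res$report, "report")
write_hulls_geojson(res$areas$hulls, "service_areas.geojson")
```

## Known limitations

* The acceptance-grade quantities that depend on the non-public registry
  (the published ITS coefficients and km² hull areas themselves) cannot be
  reproduced numerically; they serve as generator defaults and magnitude
  checks only.
* Per-base subgroup ITS is intentionally out of scope.
* The Wald-type tests rely on Gaussian monthly means; with ~85 missions
  per month the central limit theorem makes this mild, but heavy-tailed
  contamination is not modelled.
* The hull method is sensitive to single long-range missions even after
  the 95% filter; percent area changes should be read alongside the median
  distance comparisons.
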