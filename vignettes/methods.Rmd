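---
title: "Estimating the risk of dying above age 105: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the risk of dying above age 105: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longevhaz)
```

## The estimation problem

Individual records of semi-supercentenarians come from registries that
validate each case against civil documents. Three features shape the
statistics. First, everyone in the sample is there conditionally on having
survived to age 105, so the data are left-truncated and say nothing about
mortality before that age. Second, the date of death is not always known:
some individuals are only confirmed alive at a last-seen date
(right-censored). Third, some sources (US-style) withhold exact dates for
confidentiality and release only the years of birth and death with the
exact age at death in whole years and days (interval-censored). A registry
may additionally collect only deaths inside a calendar window (right
truncation).

`longevhaz` estimates the age trajectory of the hazard μ(x) above 105
without imposing any model structure on it, and quantifies uncertainty by
simulation, because at the oldest ages the handful of survivors makes
central-limit-theorem intervals untrustworthy.

## The estimator

Ages are partitioned into J left-closed intervals [x, x+δ) starting at
105. Each record enters observation at exactly age 105 and exits at its
death or last-seen age. Within each interval it contributes the
person-years it lived there (exposure); a death adds one event to the
interval containing the exact death age; a censored exit adds exposure
only. The central death rate M = E/N per interval is the
occurrence/exposure estimate of the hazard; with δ small it is
quasi-continuous. Exposures are person-time, not head counts — that is
what makes E/N a central death rate — while the number of subjects
entering each interval is reported separately as `at_risk`.

Zero-exposure intervals have no estimate (`NA`, never 0). A configurable
reporting floor (`min_at_risk`, default 10) suppresses rates and bands at
intervals entered by fewer individuals; the event/exposure counts remain
visible. The floor makes concrete the qualitative observation that a
handful of survivors cannot support a rate estimate; 10 is deliberately
permissive and the suppressed counts let readers apply a stricter rule.

The estimator assumes extinct cohorts: it applies no correction for right
truncation. The synthetic generator can *impose* a collection window, which
lets users measure how much such truncation distorts the estimate, but the
estimation step itself treats all exits as exchangeable. This mirrors how
occurrence/exposure estimation is done on historical cohorts whose members
have all died.

### Age arithmetic

Calendar ages use the civil convention: a birthday advanced by whole years
keeps month and day, with February 29 falling on February 28 in non-leap
years; the exact age is whole years plus a day count from the last
birthday. Continuous ages divide day counts by 365.25. For grid placement
the two conventions collide: the 105th birthday is not exactly
105 × 365.25 days after birth, so defining the grid age as days-since-birth
/ 365.25 would scatter cohort entry around 105.0 by a day or two. The
package therefore places every record at 105 + (days since its 105th
birthday)/365.25, which makes entry exactly 105.0 and keeps all exit ages
at or above it. Dates are proleptic Gregorian throughout (`Date`), which
is unambiguous across the 1870–1912 birth cohorts the generator emulates.

## Empirical confidence intervals

The estimated rates are transformed, assuming a constant hazard within
each interval, into cumulative death probabilities
q(x) = 1 − exp(−Σ_{i≤x} δ·M_i). A replicate simulates n individuals
multinomially into the J death intervals (probabilities are first
differences of q; the remaining mass survives past the grid and is treated
as censored at the grid end, exactly as in the observed-data transform).
Each replicate's empirical cumulative proportions are back-transformed to
rates, and the per-interval (1−level)/2 and 1−(1−level)/2 empirical
quantiles (linear interpolation between order statistics) over replicates
form the band. The percentile method is used because it is the minimal
reading of "empirical" intervals; no analytic approximation enters except
as an independent oracle in the tests.

In a replicate where all n simulated individuals die before an interval,
the rate there is undefined; such replicates are excluded from that
interval's quantiles. The number of contributing replicates is reported
per interval (`n_defined`), and bands are suppressed where fewer than half
contribute — exclusion with reporting keeps the rule transparent rather
than hiding extinction behind an arbitrary fill-in.

Defaults are 10,000 replicates at level 0.95, with n equal to the number
of records behind the estimate, so the band reflects the sampling
variability of a cohort of exactly the observed size.

## Interval-censored records and imputation

A US-style record (birth year, death year, age Y years + D days) pins the
birth date into a closed day range: the implied death date is the birth
date advanced Y calendar years then D days, and it must land in the
recorded death year while the birth date stays in the recorded birth year.
The bounds are computed analytically (with a stepping correction around
leap days) and validated in the tests against a brute-force oracle that
tries every day of the birth year. The year-addition-then-day-addition
convention is the one under which both bound computations behave
consistently at year boundaries; imputation draws the birth date uniformly
over the inclusive range, the non-informative choice given that the
registry says nothing about within-year birth seasonality.

The full pipeline repeats the imputation m times (default 1,000); each
round estimates rates from the imputed, now fully observed, records and
simulates k replicate probability sets (default 10,000). Bands are
percentiles of the pooled m × k back-transformed rate sets, so they carry
the birthdate uncertainty on top of sampling noise; the point estimate
back-transforms the mean of the m per-round probability sets, a
Rubin-style combination of the rounds' point estimates (the pooling rule
for bands does not by itself determine a point-estimate rule, so the mean
is adopted explicitly). Because the age at death in days is known exactly,
the imputed death age varies across rounds only through leap-day
placement — one or two days — so the imputation's main effect is on the
bands, not the point estimate; the tests verify both.

## The synthetic-cohort generator

The generator exists so that every downstream stage can be validated
against known ground truth while real registry data remain
access-restricted. It emulates the statistical structure of an IDL-like
population: birth cohorts 1870–1912 with birth dates uniform within the
birth year (the estimator is insensitive to within-year placement), 90%
female by default, lifespans past the 105th birthday drawn by inverse
transform from a configurable hazard regime — constant plateau (default
0.7/year, the magnitude reported for extreme-age mortality), Gompertz, or
piecewise constant — and an observation-scheme mix defaulting to 85%
fully observed, 10% right-censored, 5% interval-censored, reflecting that
validated registries consist mostly of fully observed records. Censoring
times are uniform between the 105th birthday and death, a neutral
mechanism chosen because registries do not document one. All draws come
from a single seeded stream consumed in fixed record order, so an
identical configuration and seed reproduce the dataset exactly.

What the generator does **not** emulate: age misreporting (registry
records are validated by construction), within-year birth seasonality,
country-specific collection frames beyond a simple death-date window, and
dependence between censoring and frailty. Passing tests therefore show
that the estimator recovers known hazards under clean IDL-like sampling —
not that real registry idiosyncrasies are harmless.

## Numerical choices

- Probability transforms use `expm1`/`log1p`, keeping the rate → q → rate
  round trip exact to ~1e-12 away from extinction; once q reaches 1 the
  back-transform is undefined and rates are flagged absent from that
  interval on.
- Interval membership is left-closed: a death exactly at a boundary counts
  in the interval opening there, so nothing is double-counted.
- Deaths are placed at whole days past the 105th birthday; exposures are
  continuous within intervals. The test suite pins this against a
  daily-step Lexis oracle per record (agreement within 2 days of exposure
  per interval, events exact).
- Validation is all-or-nothing per dataset: every violated field is
  reported with its row, and no partially valid record is kept. Lifespans
  at or beyond 122 years 164 days — the longest documented — are accepted
  with a warning rather than rejected, since the bound is empirical, not
  logical.

## Problem sizes used in the tests

Distributional checks run at n = 50,000 (Kolmogorov–Smirnov distance
below 0.01 against the closed-form survival), parameter recovery at
n = 20,000 (every interval with ≥ 50 at risk within 3 standard errors of
the generating hazard), the coverage study at 200 cohorts of n = 1,000
with 1,000 replicates each, and the imputation pipeline at m = 20–50
rounds on cohorts of a few thousand — sizes at which the Monte-Carlo error
of each check is small compared with its tolerance while the whole suite
stays quick to run. The shipped defaults (10,000 replicates, m = 1,000)
are the recommended analysis settings, not the test settings.

## Known limitations

- No right-truncation correction: estimates on cohorts still partially
  alive (or windowed collections) are biased toward the mortality of early
  deaths; the generator's window exists to study exactly that.
- No smoothing or parametric pooling across intervals; sparse old-age
  intervals are suppressed rather than stabilised.
- The imputation assumes uniform birth dates within the bound range;
  strong birth seasonality would tighten or shift the bands slightly.
- Sex is restricted to F/M, matching the source registries' coding.
```{r session}
sessionInfo()
```
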