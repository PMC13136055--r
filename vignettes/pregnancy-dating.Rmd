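---
title: "Dating scales and censoring-aware birth distributions in artga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating scales and censoring-aware birth distributions in artga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artga)
```

## The problem

Gestational age (GA) is counted in days from day 0, the first day of the
last menstrual period (LMP). Every dating method must be calibrated to this
origin. Population-calibrated ultrasound dating fixes the median GA at
birth at 283 days, which therefore defines the estimated date of delivery
(EDD). For pregnancies conceived by assisted reproductive technology (ART)
the oocyte-fertilization date is known exactly, and GA can be computed as

$$\mathrm{GA}_{\mathrm{ART},k} = k + c + t,$$

with $k$ the assumed median follicular-phase duration (LMP day 0 to
fertilization), $c$ the embryo-culture days (fertilization to transfer for
fresh embryo transfer, fertilization to cryopreservation for frozen
transfer) and $t$ the days from transfer to birth. The package keeps $k$ a
parameter everywhere (`K14`, `K15`); the central calibration fact — that
replacing $k$ by $k+1$ shifts every per-record GA, and hence the median
pairwise difference against ultrasound dating, by exactly one day — is an
algebraic identity that the test suite asserts exactly.

Estimating *pregnancy duration* from registry data faces a different
obstacle: 30–44% of births are nonspontaneous (inductions, elective
Cesareans, a small share of pre-labor emergency Cesareans). Dropping them
biases the birth distribution; counting them as events biases it more. The
package therefore treats spontaneous onset as the event of interest and
nonspontaneous birth as right-censoring, and estimates the survival
function with a from-scratch Kaplan–Meier product-limit estimator
(`km_fit()`), with the variance of $\log S$ accumulated by Greenwood's
formula. The key identifying assumption — censoring independent of the
latent onset time — is made explicit, and the generator can deliberately
violate it (`informative_censoring = TRUE`) to show the resulting bias.

## The synthetic registry

Real birth-registry extracts of this kind are access-restricted, so the
generator is a first-class module rather than a test fixture. It emulates,
per record:

* **Latent onset GA**: skew-normal, parameterized directly by its median so
  recovery tests are unambiguous. Defaults: medians 283 / 283 / 286 days
  for spontaneous / fresh-ET / frozen-ET conceptions, scale 16.6 days and
  shape −4, which put the central 50% of onsets within about ±7 days of
  the median with a left skew (more early than late outliers). Sampling
  uses the standard delta representation; the median of the standard
  skew-normal is found numerically from the integrated density, so no
  external distribution package is involved.
* **Follicular phase**: shifted lognormal, median 15 days, 5th–95th
  percentiles ≈ 10–26 days, right-skewed (long cycles are more common than
  very short ones). Rounded to whole days. For frozen ET the same
  distribution describes the (virtual) transfer cycle, and the thaw
  transfer is placed $c$ days after its ovulation, so the embryo's
  developmental age at transfer matches its age at cryopreservation.
* **Ultrasound dating error**: Gaussian with SD 2.5 days, added to the true
  GA at birth and rounded, because registries record whole days; recorded
  GA is truncated at 154 days (22 weeks), the cohort's inclusion floor.
* **Intervention (censoring) process**: two-part. A candidate intervention
  GA is drawn from a normal distribution centered at 279 days (SD 9,
  floored at 230) — concentrated in the late-term window where inductions
  and scheduled Cesareans actually happen — independently of the latent
  onset. A Bernoulli realization probability is then tuned numerically,
  within each group, so the expected nonspontaneous fraction matches the
  group target (defaults 30.7% / 35.5% / 44.1%). The observed birth GA is
  the minimum of latent onset and realized intervention. Under
  `informative_censoring = TRUE` the candidate is instead placed just
  before the latent onset (one day plus an exponential gap, mean 4 days),
  which couples censoring to the event time and biases the Kaplan–Meier
  median upward by well over a day — demonstrating the assumption, not an
  estimator defect.
* **Labels and covariates**: nonspontaneous births are split 73% induced,
  25% elective Cesarean and 2% pre-labor emergency Cesarean (the last
  fixed at a small share; registry descriptions give no exact figure), and
  flagged pre-eclamptic with probability 0.15 — a realistic share of
  iatrogenic deliveries — to drive the competing-risks check. Maternal
  age, parity and fetal sex are carried as plausible covariates but used
  by no estimator.

Determinism is part of the contract: identical parameters (including the
seed) give byte-identical cohorts, and the generator restores the caller's
RNG state.

**What the generator does not emulate.** Follicular-phase variation is
natural-cycle-like (5th–95th ≈ 10–26 days). In monitored ART cycles the
spread of the true fertilization day is much tighter, so the simulated
pairwise GA differences have quartile offsets of roughly ±3–4 days, wider
than the ±1.5–2 days seen in real ART registries, and the share of
|difference| ≤ 1 day is correspondingly lower. The calibration *relations*
(the 1-day $k$-shift, the median offsets, the transfer-day alignment with
a 15-day follicular phase) are unaffected, since they depend on the median
and not the spread; tests that exercise distributional shape therefore
assert those relations, not real-registry spreads. Onset GA is drawn
directly rather than as follicular phase plus a post-conception duration,
so the two are independent by construction; seasonal patterns, secular
trends and covariate effects on duration are absent.

## Exclusions and onset classification

`apply_exclusions()` applies the inclusion rules — singleton, live birth,
no registered malformation, recorded GA between 154 and 310 days, complete
ART dating information — in a fixed order, counting each record at the
first rule it trips (a malformed twin counts as a twin). This
single-counting makes the tally conserve records exactly, which the tests
assert both on constructed fixtures and at registry scale (179,810 in,
167,691 retained when the rules trip the registry-published counts). The
under-154 rule has its own tally slot: the published accounts fold it into
cohort definition rather than exclusions, but an auditable tally should
not silently merge rules.

`classify_onset()` maps spontaneous onset to "event" and induced births,
elective Cesareans and pre-labor emergency Cesareans to "censored"; it is
the single point of truth for that partition across all estimators.

## Agreement statistics

`summarize_agreement()` reports the sample median of the pairwise
differences, quartile offsets from the median (linear interpolation of
order statistics, `quantile()` type 7 — the convention is fixed and
documented because registries report one-decimal offsets), and a frequency
table of absolute differences binned as {≤1, 2, 3, 4, ≥5} days.
Fractional differences are rounded half away from zero before binning so
that a −1.5-day difference lands in the 2-day bin, matching integer-binned
registry histograms. Percentages are recomputable exactly from printed
numerator/denominator pairs, which the acceptance tests exploit.

Confidence intervals for medians of differences use a seeded percentile
bootstrap (default B = 10,000, chunked to bound memory). The method is
assumption-light and its coverage is validated by simulation (≥ 93%
empirical coverage at nominal 95% over 500 replicates of n = 5,000 draws).
A degenerate all-equal input yields a zero-width interval flagged with a
`degenerate` attribute rather than an error.

`ga_on_transfer_day_by_culture()` propagates the recorded GA at birth back
to the transfer date (`ga_at_date()` subtracts elapsed calendar days —
both scales advance one day per day). For frozen ET the thaw-transfer
date is used: propagating to the cryopreservation *calendar* date would
cross into a previous cycle and is meaningless, while the embryo's
developmental age at transfer equals its age at cryopreservation, so the
stratum medians measure the same quantity for both groups. Under a
correctly calibrated scale the day-$c$ stratum median sits near
$15 + c$ days, i.e. on the 15-day rather than the 14-day reference line,
and the day-5 minus day-2 gap is ≈ 3 days.

## Kaplan–Meier conventions

* **Ties**: events are processed before censorings at the same day (the
  standard convention); a record censored on day $t$ is still at risk for
  day-$t$ events.
* **Greenwood variance**: accumulated as $\sum d_i / (n_i (n_i - d_i))$ on
  the log-survival scale; set to `NA` once $S$ hits zero, where the log
  scale is undefined.
* **Correctness**: the estimator is checked against hand-computed fixtures
  exactly and against `survival::survfit()` to 1e−12 on 100 fuzzed
  instances with heavy ties. The reference implementation is an oracle
  only; the package never calls it for estimation.

**Median extraction.** The step median is the first observed time with
$S(t) \le 0.5$. With interpolation (the default), each recorded day $t$ is
treated as the interval $[t - 0.5, t + 0.5)$ and the cumulative
distribution is interpolated linearly within the crossing day — the
classic grouped-data median. Two properties motivated this choice over
interpolating between raw step times: (i) with no censoring it reduces
exactly to the ordinary sample median of the event times, for odd and even
$n$ alike; and (ii) on day-rounded data it removes the half-day downward
bias that raw-step interpolation produces, because the step at day $t$
represents births up to $t + 0.5$, not up to $t$. Interpolated medians are
what make fractional-day estimates (e.g. 286.1) expressible at all on
integer-day data.

Even so, the Kaplan–Meier median on day-resolution data is not exactly the
latent continuous onset median. Under the generator defaults the
large-sample estimand sits about +0.14 days from the latent 283:
smoothing a skewed distribution with rounded ultrasound error contributes
about −0.13 days, and the events-first tie convention — which credits
records censored on day $t$ with the whole day's risk — contributes about
+0.27 days at a 30% censoring fraction. Both are properties of whole-day
recording, not implementation artifacts; the recovery tests bound the
total at well under the 0.3-day tolerance used throughout.

## Monte Carlo confidence intervals for medians

The sampling model is asymptotic normality of $\log S(t)$ around the
median, with Greenwood variance. Each replicate draws a single standard
normal deviate $Z$ and perturbs $\log S(t)$ at every event step within
±10 days of the point median by $Z \cdot \widehat{\mathrm{se}}(\log S(t))$;
monotonicity is restored by isotonic regression (on the negated sequence)
and clamped at $\log S \le 0$, and the interpolated median is re-extracted.
The percentile interval of the replicate medians is the reported CI. Using
a common deviate scaled by the monotone variance profile makes the
procedure equivalent to inverting the pointwise normal band at the 0.5
crossing, which is what delivers near-nominal coverage; the window keeps
the perturbation local to where the variance profile is estimated well.

Choices worth noting:

* `n_sim` defaults to 10,000; every stochastic function requires an
  explicit seed, and pipeline sub-seeds are derived deterministically.
* For *differences* of medians (`mc_median_difference_ci()`), the two
  curves are perturbed independently, each with a substream keyed to the
  curve's own content and the caller's seed. Keying by content (rather
  than argument position) makes the estimate exactly antisymmetric under
  swapping the arguments, and makes the difference for two structurally
  identical curves exactly zero.
* Coverage is validated by simulation: 500 generator replicates at
  n = 5,000 under the default spontaneous-conception conditions, with
  truth taken as the population median of the *observable* day-resolution
  birth-GA distribution (evaluated once on a 10^6-record cohort). Judging
  interval calibration against that estimand separates it from the small
  day-resolution offset discussed above, which the recovery tests bound
  separately; against the latent continuous median the same intervals
  would fold in that fixed offset. Empirical coverage meets the ≥ 93%
  floor at nominal 95%, and the interval half-width agrees with a
  nonparametric case-resampling bootstrap within 30%.

## Censoring strategies and competing risks

`strategy_compare()` refits the same records under censor / exclude /
as-event handling of nonspontaneous births. Under the default conditions
the censoring strategy gives the largest median in every group and the
as-event bias grows monotonically as the censoring fraction sweeps from
10% to 50% — the quantitative argument for time-to-event handling.

`aalen_johansen()` estimates cause-specific cumulative incidence for
spontaneous onset versus pre-eclamptic delivery, with other nonspontaneous
births censored: $\mathrm{CIF}_k(t) = \sum_{t_i \le t} S(t_i^-) d_{ki} /
n_i$ with $S$ the all-cause Kaplan–Meier. The implementation satisfies
$\sum_k \mathrm{CIF}_k + S = 1$ at every time to 1e−12, reduces exactly to
$1 - S_{\mathrm{KM}}$ for a single cause, and matches the multi-state
Aalen–Johansen fit from the `survival` package to 1e−12 on fuzzed
instances.

## Degenerate inputs and error policy

No events at all (or of any cause) is an estimation error, not a silent
`NA`; a curve whose survival never reaches 0.5 raises an undefined-median
error that the pipeline converts to a flagged missing value with a reason;
empty agreement input is an error while an all-equal input is a flagged
zero-width interval; schema violations in a registry CSV produce per-row
diagnostics and abort the read. Mixture weights, fractions and scales are
validated at parameter-construction time.

## Problem sizes

The test suite exercises recovery at n = 50,000 (median within 0.3 days;
frozen-minus-fresh separation within 0.3 days), coverage at 500 × 5,000
with 1,000 Monte Carlo replicates per interval, oracle equivalence on 100
fuzzed instances up to n = 200, and strategy sweeps at 20,000 records per
censoring fraction — sizes at which Monte Carlo error is comfortably below
the asserted tolerances while the full suite runs in minutes on one core.

## Known limitations

* The ultrasound GA at birth is an input (as in registries); the package
  contains no fetal-biometry model, and no covariate adjustment
  (quantile-regression or otherwise) — grouping columns are carried so
  users can stratify externally.
* The pairwise-difference spread of simulated ART cohorts is wider than in
  real monitored-cycle registries (see the generator section); analyses
  that depend on that spread, rather than on medians and calibration
  relations, should not be benchmarked against the generator defaults.
* The Monte Carlo CI realizes one specific reading of "normal perturbation
  of log-survival around the median" (common deviate, ±10-day window,
  isotonic repair); it is validated by coverage and bootstrap agreement,
  not by digit-level agreement with any published interval widths.
* Frozen-ET culture days are drawn from {2, 3, 5}; the schema accepts any
  nonnegative integer (day-6 blastocysts exist in real data), but the
  generator does not produce them.
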