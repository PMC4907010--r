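---
title: "Measuring ED crowding from arrival and departure timestamps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ED crowding from arrival and departure timestamps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcrowd)
```

## The model

`edcrowd` treats an emergency department as a queueing system observed only
through event timestamps. A patient is "present" from electronic
registration at the front desk (arrival) to registration of departure.
Dividing the study period into intervals of width 30 min and counting
arrivals $A(t)$ and departures $D(t)$ per interval, the census at the start
of the next interval follows the integer recursion

$$Q(t+1) = Q(t) + A(t) - D(t), \qquad Q(0) = 0.$$

This is the *black-box* model: one queue, two timestamps, no behavioural
assumptions. Crowding statistics are then built not from the raw census but
from the **maximum queue per shift** — the worst half-hour of each 8-hour
shift — because crowding is about peaks, not averages: the risk of reaching
100 % bed occupancy *at least once* during a shift is exactly the
exceedance probability of the shift maximum.

Three conventions are forced by the recursion's timing and are applied
consistently everywhere:

* **Half-open intervals.** An event at time $x$ belongs to the unique
  interval with start $\le x <$ start + width; an event exactly on a
  boundary belongs to the interval starting there.
* **Start-of-interval census.** $Q(t)$ reflects only events in intervals
  $0..t-1$. A patient arriving and departing strictly inside one interval
  never appears in any $Q$. The independent census oracle therefore counts
  a patient as present at interval start $s$ iff entry $< s \le$ exit;
  with that convention `census_oracle()` equals the recursion elementwise
  whenever all events fall inside the grid, and the equality is
  property-tested on randomized record sets.
* **No clamping.** Patients present before the period start are invisible
  under $Q(0)=0$, so the early census can undercount or even go negative.
  Negative values are returned unchanged with a warning; clamping would
  silently break the conservation identity
  $q_0 + \sum A - \sum D = Q(\text{final})$. The standard mitigation is the
  burn-in discard below.

### Extended queues

Where triage and early-warning-score (EWS) assessments are registered, the
stay splits into four sub-queues bounded by surrogate markers: arrival →
triage (Q1, waiting for initial assessment), triage → first EWS (Q2,
waiting for a doctor), first → last EWS (Q3, in examination/treatment),
last EWS → departure (Q4, waiting to leave). Any `(entry, exit)` timestamp
pair defines a queue via `queue_definition()`. On complete, ordered records
the sub-queue censuses sum exactly to the black-box census (the sub-stays
partition the stay); a record violating the idealised order is excluded
only from the queues whose bounds it violates, never dropped from the
black-box flow.

Routine registrations are typically very incomplete here.
`classify_flow()` partitions records into four exhaustive, mutually
exclusive categories: *complete* (all three surrogate timestamps),
*triage_only* (triage present, EWS chain incomplete), *ews_no_triage*, and
*blackbox_only*. The marginal triaged share is *complete* + *triage_only*.
The category definitions are chosen so that every record lands in exactly
one bin even when, say, a first EWS is present but the last is not.

## Shifts, days and strata

Operational days begin with the day shift at 07:00; shifts last eight
hours (day 07:00–14:59, evening 15:00–22:59, night 23:00–06:59). The night
shift is attributed to the operational day on which it began, so Monday
02:30 belongs to Sunday's night shift. Saturday and Sunday day/evening
shifts are weekend shifts; for nights the weekend is Friday and Saturday
night. Seasons split the year at April 1 and October 1 (summer =
April–September).

Because the recursion starts empty, all queue analyses discard the first
three shifts (24 h) by default (`burn_in_shifts = 3`). A full shift holds
16 half-hour intervals; partial leading/trailing shifts are kept and
flagged via `n_intervals < 16`.

Two numerical choices matter for reported tables:

* **Quantiles** use the linear-interpolation definition
  (`stats::quantile()` type 7), so an IQR of 4.25 on integer maxima is
  representable. This is the only family of definitions that can produce
  such values; tests check the medians and IQRs against an independent
  interpolation oracle.
* **Patient-to-nurse ratios** are rounded half-away-from-zero to one
  decimal (20/7 → 2.9, 7/4 → 1.8). Base R's banker's rounding would
  disagree on exact halves.

A shift spanning two roster bands (the weekday day shift covers a 7-nurse
morning band for five hours and an 8-nurse band for three) is attributed
the **majority band**; ties go to the band in force at the start of the
shift. The alternative band's count and ratio are reported alongside, so
tables can quote both figures.

## Crowding risk

`exceedance_risk()` reports, per stratum, the share of shifts whose max
queue reached the capacity threshold. The comparison is `>=`: a queue of 19
in 19 beds is 100 % occupancy. For integer maxima the risk equals
$1 - F(\text{threshold} - 1)$ with $F$ the stratum ECDF; this identity is
property-tested, and risk is non-increasing in the threshold by
construction. No confidence bands are attached — the method reports point
estimates, and the ECDF is deliberately left non-parametric.

## Statistical toolkit

* **Fisher's index of dispersion** (variance/mean of interval counts;
  $(n-1)\,\hat I \sim \chi^2_{n-1}$ under Poisson) checks the Poisson
  assumption on arrivals. The verdict is two-one-sided (over/under/equi at
  `alpha`), although over-dispersion is the direction that matters in
  practice: over-dispersed arrivals mean Poisson-based capacity models
  understate peak load. Calibration is tested by simulation: under a
  Poisson null the type-I error of the upper-tail test stays within two
  Monte-Carlo standard errors of 0.05 across 2,000 replicates, and the
  index recovers a configured negative-binomial variance/mean ratio of 2
  within ±0.1.
* **Spearman's rho** (mid-rank Pearson) measures carry-over. The p-value is
  an exact permutation p for $n \le 10$ without ties and the
  t-approximation otherwise — shift-level analyses have hundreds of pairs,
  firmly asymptotic territory, while exactness helps in toy examples.
  Constant input yields a flagged `NA` rather than an error.
* **Carry-over pairings** match each source shift with the immediately
  following target shift on the correct operational day (day→evening and
  evening→night within a day; night→day and day→day across consecutive
  days; day-level arrival totals across consecutive days). Missing
  partners drop the pair — no interpolation across gaps or the burn-in
  boundary. Fewer than three pairs is an error: a correlation without a
  testable sample size invites over-interpretation.
* **Kruskal–Wallis** (tie-corrected) compares max-queue distributions
  across shifts, day classes or seasons. No multiple-testing correction is
  applied; the analyses are descriptive.

## The synthetic visit generator

`simulate_ed()` exists so that every pipeline stage is testable and
calibratable without patient data. It emulates the structural features
that drive the statistics:

* a **non-homogeneous arrival process** at 30-min resolution — a diurnal
  weight profile per day class times a daily mean — with selectable
  Poisson or **negative-binomial** interval counts (mean $\mu$, dispersion
  $k$, variance $\mu + \mu^2/k$);
* a **log-normal length of stay** truncated to [1 min, 48 h] by
  inverse-CDF (not clamping, which would pile mass on the bounds);
* **ordered surrogate timestamps** at cumulative Dirichlet fractions of
  the stay, so records always satisfy the order invariants *before*
  missingness;
* **independent per-field missingness** for the three surrogate
  timestamps;
* attribute draws (age mixture, sex, triage score, trauma flag).

Defaults were fixed once as the study conditions: 114/115 mean arrivals
per weekday/weekend day, negative-binomial counts with $k = 5$ (interval
counts in real EDs are consistently over-dispersed), stay median 2 h with
log-scale SD 0.8, and missingness marginals (0.718, 0.879, 0.906) matching
the registration rates of routine triage/EWS data. One known gap is
deliberate: with *independent* per-field missingness the joint
"neither triage nor EWS" share is the product ≈ 63 %, whereas real
registration gaps are positively dependent (a patient skipped at triage
tends to be skipped downstream), which pushes the joint share higher
(≈ 71 % in the registration pattern the flow classifier is tested
against). The generator matches marginals, not the dependence structure.

Reproducibility: a single seed feeds per-stage substreams (arrivals,
stays, gaps, attributes, missingness), so identical specs give
byte-identical CSVs and changing one probability never perturbs the other
streams — both properties are tested.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no service-slowdown feedback under crowding (no
state-dependent length of stay), no boarding of admitted patients, no
registration-delay artefacts (batched arrivals at busy times), no
day-to-day autocorrelation beyond what the shared diurnal profile induces,
and no dependence between missingness fields. Conclusions about a real ED
require the real timestamps; the simulator certifies the machinery, not
the epidemiology.

## Problem sizes

The test suite exercises the oracle equivalence on 1,000 randomized record
sets, dispersion calibration on 2,000 Poisson replicates of 10,000 counts,
carry-over null calibration on 1,000 replicates of 120 shift pairs
(continuous maxima, which isolate the test's calibration from rank-tie
granularity), and several multi-week simulated pipelines; the whole suite
runs in well under a minute. The acceptance script simulates one full year
(≈ 42,000 visits, 17,520 intervals) in about two seconds.

## Limitations

The method measures census against capacity; it does not model *why*
queues form (input vs throughput drivers must be read off the A/D/Q
series), it attributes roster nurses rather than nurses actually present,
and the black-box census counts all patients equally regardless of
acuity. Same-minute arrival/departure registrations are accepted as
zero-length stays. Timestamps are naive local wall-clock at minute
precision with uniform 48 intervals per day; daylight-saving days are
accepted as-is rather than re-aligned.
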