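# edcrowd

Queue-based analysis of emergency department (ED) crowding from
patient-level timestamps.

Crowding — the state in which treatment demands exceed an ED's beds and
staff — is usually studied with site-specific models that are hard to
transplant. `edcrowd` implements a deliberately generic alternative that
needs only the two timestamps every ED records reliably: time of arrival
and time of departure. For clinicians and health-services researchers it
turns a year of routine registrations into shift-level crowding risks,
staffing ratios and carry-over diagnostics; for methodologists it ships a
fully seeded synthetic visit generator so every stage can be exercised and
calibrated without hospital data.

## The method

The study period is divided into intervals of width Δ = 30 min. With
A(t) arrivals and D(t) departures counted in interval t, the number of
patients present (the queue length) at the start of the next interval is

    Q(t+1) = Q(t) + A(t) − D(t),      Q(0) = 0,

in exact integer arithmetic. Because the recursion starts empty, the first
24 h (three 8-hour shifts) are discarded as burn-in. An independent census
cross-check — directly counting patients with entry < s ≤ exit at every
interval start s — is built in and must agree with the recursion exactly.

From the interval series the package derives, per operational day (starting
07:00) and shift (day 07:00–14:59, evening 15:00–22:59, night 23:00–06:59,
with Friday and Saturday nights counted as weekend):

* **max queue** — the largest interval census within the shift;
* **exceedance risk** — the share of shifts whose max queue reached bed
  capacity, i.e. `1 − F(capacity − 1)` of the stratum's empirical CDF
  ("probability of at least one interval at ≥ 100 % bed occupancy");
* **patient-to-nurse ratios** from a duty-roster configuration;
* **carry-over** — Spearman rank correlation of max queues in successive
  shifts/days;
* **Kruskal–Wallis** comparisons across shifts, day classes and seasons,
  and **Fisher's index of dispersion** (variance/mean of interval counts;
  1 under Poisson) to check the Poisson assumption on arrivals.

Where richer registrations exist, the single "black-box" queue generalises
to four sub-queues bounded by surrogate markers — triage time and the first
and last early-warning-score (EWS) assessment — representing waits for
initial assessment (Q1), for a doctor (Q2), for treatment completion (Q3)
and for departure (Q4). On complete, ordered records the four sub-queue
lengths sum exactly to the black-box census.

## Worked example

Two months of synthetic visits, aggregated and analysed against the bundled
19-bed roster:

```r
library(edcrowd)

spec   <- simulation_spec("2013-01-01 00:00", "2013-03-01 00:00", seed = 42)
visits <- simulate_ed(spec)          # 6,737 visits
grid   <- make_interval_grid("2013-01-01 00:00", "2013-03-01 00:00")
iv     <- aggregate_table(visits, grid)
roster <- default_roster()
shifts <- max_queue_per_shift(iv, burn_in_shifts = 3, roster = roster)

exceedance_risk(shifts, roster$bed_capacity)
#>     shift weekend n_shifts       risk threshold
#> 1     day   FALSE       42 0.97619048        19
#> 2 evening   FALSE       42 0.92857143        19
#> 3   night   FALSE       43 0.02325581        19
#> 4     day    TRUE       16 0.87500000        19
#> 5 evening    TRUE       16 1.00000000        19
#> 6   night    TRUE       16 0.00000000        19

carry_over(shifts, "day_to_evening")
#> Carry-over (day_to_evening): rho = 0.480, p = 0.0001382, n = 58 pairs

fisher_dispersion(iv$A_blackbox)
#> Fisher's index of dispersion: 2.699 (n = 2832, mean = 2.38)
#>   chi-square = 7639.9 on 2831 df; p(over) = 0, p(under) = 1
#>   verdict at alpha = 0.05: over-dispersed
```

Reading: under this simulation's default load (≈114 arrivals/day into 19
beds, over-dispersed arrivals, 2 h median stay) nearly every weekday day
and evening shift sees at least one half-hour at or over 100 % bed
occupancy, while night shifts almost never do; a long day-shift queue
predicts a long evening-shift queue (ρ = 0.48); and interval arrival
counts are far from Poisson (index ≈ 2.7), so Poisson-based capacity
models would be mis-calibrated here.

File-based pipelines use `run_simulate()`, `run_aggregate()` and
`run_analyze()` (CSV in, CSV + JSON manifests out); a thin command-line
wrapper ships in `inst/cli/edcrowd.R`.

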