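# periomop

Perioperative anesthesia data in the OMOP common data model.

`periomop` is for clinical data engineers and perioperative researchers
who want to standardize anesthesia data — AIMS exports (operation steps,
drug administrations, 30-second monitor samples, consultation notes) and
hospital-discharge records (stays, unit moves, ICD-10 diagnoses,
procedures) — into an OMOP CDM subset extended with two tables for
secondarily computed data:

* **PERIOD**: an interval defined by two milestone events, by an event ±
  a fixed offset, or by a threshold rule on a monitor signal;
* **FEATURE**: a scalar defined by three concepts — a period, a raw
  signal and an aggregation method (mean, median, min, max, range,
  episode count, time beyond threshold, area beyond threshold).

The signature computation is hypotension burden. For a signal sampled
every Δt = 30 s and a rule "MAP < 65 mmHg", maximal runs of samples
strictly below threshold become episodes (runs separated by ≤ a gap
tolerance merge, runs shorter than a minimum duration drop), and over a
period window *P*:

* time below threshold = Σ episode durations clipped to *P* (seconds),
* AUC below threshold = Σ over qualifying samples of
  (65 − MAP<sub>i</sub>) · Δt<sub>i</sub>, rectangular (sample-and-hold)
  integration, in mmHg·min.

On top of the store the package implements the eight audit/research
queries (operations per year and department; outpatient anesthesia;
fast-track without PACU; hypotension within 30 min of induction; rescue
vasopressors within 15 min of the first MAP drop; length of stay by ASA
status; ICU stay after surgery; Mallampati grades parsed from notes) and
four dashboard indicator sets (population, hemodynamics, ventilation —
tidal volume per kg Devine ideal body weight — and postoperative
outcome). A seeded synthetic source generator with recorded ground truth
stands in for a real warehouse and makes every query exactly checkable.

## Worked example

```r
library(periomop)

reg <- load_registry()           # packaged concept registry
coverage_report(reg)
#>   category        n_source n_mapped n_added pct_mapped
#> 1 demographics          23       23       0      100
#> 2 visits                 6        5       1       83.3
#> ...
#> 7 period                18        5      13       27.8
#> 8 feature              155        0     155        0
#> 9 total                522      353     169       67.6
```

522 source concepts; 353 map to standard OHDSI concepts, 169 (the
periods, the features and the "operating room visit" visit type) are
site-local concepts with ids ≥ 2,000,000,000. Percentages are recomputed
from counts.

```r
detect_episodes(c(0, 30, 60, 90, 120), c(70, 60, 60, 70, 60),
                map_hypotension_rule())
#>   start   end duration_s n_samples extremum
#> 1    30    90         60         2       60
#> 2   120   150         30         1       60

compute_feature(list(start = 0, end = 150), c(0, 30, 60, 90, 120),
                c(70, 60, 60, 70, 60),
                aggregation_spec("auc_beyond_threshold",
                                 map_hypotension_rule(), "UNIT_MMHG_MIN"))
#>   value_as_number unit_code     n_samples
#> 1             7.5 UNIT_MMHG_MIN         5
```

Two episodes (half-open intervals, the second closed at the last sample
plus one 30-s interval) and an area of 3 × 5 mmHg × 0.5 min = 7.5
mmHg·min. Full pipeline on a synthetic bundle:

```r
gb <- synth_generate(synth_config(n_patients = 50, seed = 1))
store <- cdm_create()
run_etl(gb$bundle, reg, store)   # rows_read = rows_written + rows_rejected
derive_periods(store, reg)
compute_feature_set(store, reg)

q5_rescue_drugs(store)
#>   ingredient     n_administrations
#> 1 atropine                       5
#> 2 dobutamine                     3
#> 3 ephedrine                      1
#> 4 epinephrine                    4
#> 5 norepinephrine                 1
#> 6 phenylephrine                  1

hemodynamics_summary(store)$indicators
#>   rule         n_operations
#> 1 MAP<65 mmHg            40
#> 2 MAP>120 mmHg            0
#> 3 HR<60 bpm               7
#> 4 SpO2<90 %               4
```

`q5` counts rescue-drug administrations falling in the 15 minutes after
each operation's first hypotension period; the hemodynamics dashboard
counts operations with at least one episode per rule, all from FEATURE
rows. `gb$truth` holds the generator's bookkeeping (injected episode
boundaries, outpatient/fast-track/ICU flags, rescue latencies), and
every query output above matches it exactly.

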