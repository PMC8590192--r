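---
title: "Standardizing perioperative data into an extended OMOP CDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing perioperative data into an extended OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anesthesia information management systems (AIMS) record the operating room
at high frequency — one sample every 30 seconds for monitored vital signs
and ventilation parameters — alongside drug administrations, procedural
milestones and free-text consultation notes. Hospital discharge systems
(in France, the PMSI) describe the surrounding stay: unit moves, ICD-10
diagnoses, procedures, admission and discharge. Reusing these data for
audit and research across centers requires a common representation.
`periomop` standardizes both sources into a subset of the OMOP common data
model (CDM), extended with two tables that the standard model lacks:

* **PERIOD** — an interval of clinical interest, defined either by two
  milestone events (a start event and an end event, e.g. start and end of
  anesthesia), by one anchor event plus a signed offset (e.g. the 30
  minutes following induction), or by a threshold rule applied to a
  monitor signal (e.g. an episode of mean arterial pressure below
  65 mmHg).
* **FEATURE** — a scalar defined by the combination of three concepts: a
  period, a raw signal and an aggregation method. The aggregation is
  either a plain statistic (mean, median, minimum, maximum, range) or an
  expert rule (number of episodes, time spent beyond a threshold, area
  between the signal and the threshold).

Raw monitor samples are deliberately kept **out** of the OMOP clinical
tables, in a `WAVEFORM` side store, so that queries over the clinical
tables stay fast and the row-per-fact tables are not flooded; everything
the audit queries need is first condensed into PERIOD and FEATURE rows.

## Semantic mapping and the concept registry

The source vocabulary is organized in eight categories: patient
characteristics on the day of the procedure, visit types, units,
monitored parameters, operation steps, drugs, periods and features. The
packaged registry (`load_registry()`) carries 522 source concepts with
their mapping status: 353 map to standard OHDSI concepts (drugs at the
RxNorm *ingredient* level, since the clinical drug form is not reliably
documented in an AIMS) and 169 — essentially every period and feature
concept, plus the "operating room visit" visit type — exist only locally
and are created in the site-local concept id block starting at
2,000,000,000 (`add_local_concept()`). Because the original concept list
is not public, the registry's *names* outside the concepts the package
itself uses are synthetic placeholders; the per-category counts and
mapped/added splits are the real accounting. `coverage_report()`
recomputes every percentage from the counts rather than echoing published
figures (5/18 mapped periods is reported as 27.8%, and 353/522 as 67.6%).

## Structural mapping

`run_etl()` routes each source table to its CDM target: stays to
`VISIT_OCCURRENCE`; unit moves and operations to `VISIT_DETAIL`, with
operations tagged by the local "operating room visit" concept so they can
be told apart from care-unit visits; diagnoses (and the ASA status) to
`CONDITION_OCCURRENCE`; drug administrations to `DRUG_EXPOSURE`;
operation steps to `PROCEDURE_OCCURRENCE`; day-of-procedure
characteristics to `OBSERVATION`; consultation text to `NOTE`; monitor
samples to the `WAVEFORM` side store only. ASA is written to both
`OBSERVATION` (it is a day-of-procedure characteristic) and
`CONDITION_OCCURRENCE` (the length-of-stay audit query sources it from
conditions). ICD-10 and CCAM codes pass through with concept id 0 and the
source value preserved: they are externally standardized terminologies
whose mapping is not this package's concern. Operating rooms are linked
to their specialty department through a dedicated `CARE_SITE_LINK`
relation, one row per room.

Every id the ETL assigns is a deterministic function of the source keys
(`person_id` = patient id, `visit_occurrence_id` = stay id, operating-room
`visit_detail_id` = 500000 + operation id), so re-running the ETL on the
same inputs reproduces the same store bit for bit. Rows that cannot be
resolved — an unregistered drug code, an operation pointing to a missing
stay — are rejected into a quarantine table attached to the ETL report
(optionally written to a file), and the report satisfies
`rows_read = rows_written + rows_rejected` for every target table, where
`rows_read` counts attempted target rows (a single operation fans out
into six OBSERVATION rows and each is accounted for individually).

The store itself is an in-memory relational bundle — a named list of
tibbles with reference semantics — persisted as a directory of
comma-separated UTF-8 files, one per table, with ISO 8601 datetimes and
empty fields for NULL (`cdm_write()` / `cdm_read()` round-trip
losslessly). All datetimes are timezone-naive local clock times and all
intervals are half-open `[start, end)`. `cdm_integrity_check()` verifies
the structural contracts after every stage: foreign keys resolve, every
visit detail lies inside its parent visit occurrence window, every
clinical event carries a resolvable visit detail, periods are ordered,
features resolve to a period of the same person and visit with a finite
value, every room links to exactly one department, and no waveform signal
concept ever appears in `OBSERVATION`.

## Episode detection

`detect_episodes()` is the core intraoperative computation. Its
semantics, stated once and tested against an independent brute-force
oracle:

* values outside the rule's plausibility bounds are dropped as artifacts
  (defaults: MAP 20–250 mmHg, HR 10–300 bpm, SpO2 40–100%), as are
  missing values;
* a sample qualifies when it satisfies the comparator **strictly**
  ("MAP < 65" excludes 65.0);
* two qualifying samples continue one episode iff their time difference
  is at most the nominal interval (30 s) plus the gap tolerance;
* an episode ends at the first disqualifying sample's time when that
  sample lies within the same span; when a data gap or the series end
  terminates it, it ends at the last qualifying time plus one nominal
  interval;
* runs separated by at most the gap tolerance are merged, and episodes
  shorter than the minimum duration are then discarded.

The published source does not state a minimum episode duration, a merging
rule or an artifact filter; the package's defaults are 0 s, 0 s and the
bounds above, all configurable per `threshold_rule()`. With zero minimum
duration, raising the gap tolerance never increases the episode count;
with a positive minimum duration that monotonicity can break (two
sub-threshold-duration runs can merge into one countable episode), which
is why the property suite tests the two knobs separately.

Durations and areas use rectangular (sample-and-hold) integration rather
than trapezoidal: a 30-second monitor snapshot is a step-wise signal by
nature, and the rectangular rule makes the per-sample oracle exact. Each
qualifying sample holds its value until the next sample, for at most one
nominal interval (missing samples contribute no time and no area),
clipped at the window end. Consequences worth knowing: time below
threshold equals the summed durations of the detected episodes clipped to
the window (an identity the tests assert), and the area is additive over
any partition of the window whose cut points lie on the sampling grid —
each sample's rectangle belongs to the window containing the sample, so a
cut strictly inside a holding interval would move that rectangle's tail
into the earlier part. Areas are reported in signal-unit × minutes
(7.5 mmHg·min for the worked five-sample example in the README).

Tidal volume indicators normalize by ideal body weight. The published
dashboards use ml/kg IBW without defining IBW; the package uses the
Devine estimate (`50 + 0.91·(height − 152.4)` kg for males, 45.5 for
females), the convention in the protective-ventilation literature.

## The synthetic source generator

No perioperative warehouse is publicly available, so the package ships a
seeded generator (`synth_generate()`) whose defaults are the study
conditions of the validation suite: 200 patients, 15% with a second
operation, operations of 45–180 min between 2018 and 2021 on a fixed
step template (anesthesia start, induction +5 min, intubation, incision
+20 min, closure, anesthesia end, PACU in/out), 30-second sampling of
MAP, heart rate, SpO2 and expiratory tidal volume, 20% outpatient stays,
12% urgent operations, 10% postoperative ICU transfers, 15% fast-track
(no PACU), 3% in-hospital deaths, ASA distributed 25/45/22/7/1% over
classes 1–5 and Mallampati 40/35/18/7% over I–IV with 2% unparseable
notes. Signals are a per-operation Gaussian baseline plus truncated
Gaussian noise with **rectangular** injected deviations for episodes:
hypotension episodes (0–3 per operation, 2–10 min, ≥5 mmHg below
threshold, grid-aligned, separated by ≥120 s) are pushed below 64 mmHg
while background noise is clamped above 68 mmHg. Rescue vasopressor
administrations follow the first episode with probability 0.75, within
the 15-minute window with probability 0.8 (1–14 min) and otherwise at
16–25 min, so the drug query has both members and non-members.

The point of the clamping is that episode recovery is unambiguous *by
construction*: the detector must recover every injected episode count and
boundary exactly, and every query's membership set must equal the
generator's bookkeeping exactly — any discrepancy is a bug, not noise.
The price is realism: real arterial lines produce artifacts, drift,
beat-to-beat variability and genuinely ambiguous threshold grazing, and
real warehouses have orders of magnitude more records (the validation
bundle yields roughly 230 operations against the hundreds of thousands in
a production warehouse, and ~15 features per operation against a full
155-concept catalogue). Passing the recovery suite therefore demonstrates
the correctness of the plumbing and of the episode/feature algebra on
step-wise signals, not robustness to messy clinical waveforms — the
artifact bounds are the only waveform-level cleaning implemented.

A note templated as `"Mallampati: <grade>"` emulates the structured
free-text parsing the note query performs; unparseable notes are counted
as "unknown" rather than dropped.

## Numerical and design choices

* Half-open intervals everywhere; "within 30 minutes" includes minute 0
  and excludes minute 30.
* The "first drop" in the rescue-drug query is the earliest hypotension
  period start per operation; ties are broken by period id.
* Outpatient status is carried on the visit occurrence's visit-type
  concept; the urgency flag travels as an OBSERVATION from the AIMS side.
* Threshold-rule features are identified by rule-specific feature
  concepts ("time with MAP<65 mmHg", ...) rather than by the generic
  aggregation concept, because a (period, signal, generic-aggregation)
  triple cannot distinguish MAP<65 from MAP>120.
* Per-operation tidal volume is summarized as the median over the
  anesthesia period before dividing by IBW (the within-operation reducer
  is not specified in the published dashboards).
* Zero-length milestone periods (coincident start and end events) are
  kept but flagged in the derivation log; a missing milestone yields no
  period and a log entry.
* `derive_periods()` and `compute_feature_set()` replace their output
  tables deterministically, so re-running them is idempotent.

## Validation

`tests/testthat` exercises each module and, in `test-acceptance.R`, the
end-to-end contract: the registry accounting; detector ≡ oracle on 1000
random series (uneven spacing, missing values, artifacts, both
comparators, random gap/minimum-duration settings); exact recovery of
episodes and of all eight query membership sets on the 200-patient
bundle; the conservation identities; and a clean integrity check after
every stage. `scripts/acceptance.R` recomputes the same quantities from
scratch against the installed package and writes them as JSON. Problem
sizes (200 patients, ~230 operations, ~220k monitor samples, 1000 oracle
series) are the package's chosen validation scale: large enough for every
query to have members and non-members under the configured rates, small
enough to run in well under a minute each.

## Known limitations

* Templated note parsing only; no general clinical NLP.
* The feature plan covers the named examples (hypotension burden,
  MAP/HR/SpO2 rules, tidal volume), not a full feature catalogue.
* No OHDSI tool-stack integration (Athena, Achilles, ATLAS); PERIOD and
  FEATURE are local extensions invisible to standard OHDSI software.
* Single-site id spaces; no multi-site reconciliation or incremental ETL.
* The synthetic generator emulates structure, not physiology (see above).
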