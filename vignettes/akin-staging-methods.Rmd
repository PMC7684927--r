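---
title: "Event-driven AKIN staging: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven AKIN staging: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akiflow)
```

`akiflow` computes event-driven acute kidney injury (AKI) stage time series
for ICU encounters from routinely charted urine output and serum creatinine,
following the Acute Kidney Injury Network (AKIN) criteria, and builds the
encounter- and cohort-level outcome metrics used in before/after evaluations
of AKI decision support: admission/discharge/maximum stage, per-day stage
maxima, stage-progression rates, time-to-AKI curves, and eGFR-based
enoxaparin dose compliance. This vignette is the package's account of the
underlying models, the conventions that had to be fixed where the criteria
are silent, and the design of the synthetic cohort generator that makes the
whole pipeline testable without access to clinical data.

## The staging model

Two stage streams are computed per encounter and combined.

**Creatinine staging (AKI Cr).** Every serum creatinine measurement $c$ is
compared with the baseline creatinine $b$:

* stage 3 if $c/b > 3$, or $c \ge 4.0$ mg/dL with an acute rise
  $c - b \ge 0.5$ mg/dL;
* stage 2 if $c/b > 2$;
* stage 1 if $c/b \ge 1.5$ or $c - b \ge 0.3$ mg/dL;
* stage 0 otherwise.

The boundary conventions follow AKIN's printed ranges ("1.5–2", "> 2–3",
"> 3"): the stage-1 ratio bound is inclusive, the stage-2 and stage-3 bounds
are strict. Stages are **not ratcheted**: the stream reports the current
state, so the stage falls when creatinine falls.

**Urine-output staging (AKI UO).** Charted urine volumes are converted to an
hourly weight-normalised rate grid (mL/kg/h; see below) and trailing windows
ending at each hour are evaluated:

* stage 3 if the trailing 24-h mean rate is below 0.3 mL/kg/h, or every hour
  of the trailing 12 h is anuric;
* stage 2 if the trailing 12-h mean is below 0.5 mL/kg/h;
* stage 1 if the trailing 6-h mean is below 0.5 mL/kg/h;
* the emitted stage is the maximum satisfied stage; a window is eligible
  only if every hour in it has charting coverage.

**Combined stage.** At every timestamp where either stream updates, the
combined stage is the maximum of the two streams' most recent values; a
stream with no value yet contributes 0. This is the "current state" the
bedside display would show, and all outcome metrics are computed from it.

## Conventions the criteria leave open

The AKIN text does not fully determine an executable algorithm. The
following choices are explicit, configurable through `staging_rules()`, and
exercised by the tests:

* **Mean-rate windows.** "Urine output below 0.5 mL/kg/h for 6 h" is read as
  the trailing-window *mean* falling below the threshold, the common
  electronic-sniffer reading, robust to single-hour charting spikes. The
  stricter every-hour-below reading is available as
  `uo_window_mode = "all_hours"`.
* **Window length.** "For more than 6 h" is evaluated as a window of exactly
  6 h ending at each hour boundary, so the first qualifying evaluation
  occurs after more than 6 h of low output; likewise 12 h and 24 h.
* **Anuric hour.** An hour with less than 1 mL absolute output (not exactly
  zero) counts as anuric, tolerating charting noise.
* **Missing hours invalidate windows.** Hours without charting coverage make
  every window containing them ineligible. Counting them as zero would
  fabricate anuria out of non-charting.
* **Half-open intervals.** Hour $h$ covers $[h-1, h)$ hours after admission;
  ICU day $k$ covers $[24(k-1), 24k)$; an event on a boundary belongs to the
  later interval.
* **Threshold guard.** Window means are compared against thresholds with a
  $10^{-9}$ guard, so a mean exactly at a threshold is never "below" it
  regardless of floating-point accumulation order.

**Urine charting gaps.** Each charted volume is spread uniformly over the
interval since the previous urine charting (or admission, for the first
event), up to a pooling cap `uo_max_pool_h` (default 6 h, the longest
accumulation period that is still plausibly a deliberate pooled
measurement). When the gap since the previous charting exceeds the cap, the
volume is attributed to the trailing cap hours and the earlier hours of the
gap have no coverage — they are missing, not zero. Hours after the last
urine event are likewise outside the grid. This is the one place where two
reasonable readings of "accumulated since the previous charting" collide: a
literal unlimited spread can never produce an uncovered hour between events,
yet long silent gaps are clearly not continuous collection. The cap
reconciles the two and is configurable.

## Baseline creatinine

Creatinine staging needs a pre-illness baseline. When one is charted it is
used as given. Otherwise the baseline is back-calculated from the
four-variable re-expressed MDRD equation,

$$\mathrm{eGFR} = 175 \cdot \mathrm{SCr}^{-1.154} \cdot \mathrm{age}^{-0.203}
\cdot 0.742^{[\mathrm{female}]} \cdot 1.212^{[\mathrm{Black}]},$$

inverted at an assumed-normal eGFR of 75 mL/min/1.73 m², the established
convention for MDRD baseline estimation. The coefficient (175 for
IDMS-aligned creatinine), the assumed eGFR and the use of the race
coefficient are all configurable; the inversion is exact (closed form) and
tested to $10^{-9}$ relative tolerance across the demographic grid.
Creatinine is handled internally in mg/dL (1 mg/dL = 88.42 µmol/L), with the
file unit system declared once per file.

## The exclusion cascade

Encounters are excluded, in fixed order, for: stay not exceeding 24 h;
missing age, sex or race; age above 90; AKI on admission, defined as mean
weight-normalised urine output below 0.5 mL/kg/h over the first 6 h with
full charting coverage of that window (the criteria name "oligoanuria on
admission" without a number; 0.5 mL/kg/h is the stage-1 oliguria threshold
and is configurable); renal replacement therapy at any point of the stay
(RRT confounds both stage streams); and insufficient data to compute at
least one stage stream (no creatinine and no urine-output-with-weight).
Every excluded encounter is counted once, under the first criterion it
fails, so the counts conserve the cohort size and the cascade is idempotent.
The enoxaparin module applies its own eligibility filter (RRT, weight over
100 kg) independently of this cascade, because the two analyses exclude on
different grounds.

## Enoxaparin dose compliance

Each administered (nonzero) enoxaparin dose is judged against the most
recent eGFR at or before the administration time: correct when the dose does
not exceed the recommended daily dose for that eGFR. The default
recommendation table has three half-open bands — 40 mg/day at eGFR ≥ 30,
20 mg/day in [20, 30), nothing below 20 — reconstructed from the two
printed anchors of the dosing-error analysis (20 mg is correct in the 20–30
band; nothing is correct below 20) plus the standard 40 mg prophylactic
dose; the full table is user-configurable. Band boundaries are half-open
with the lower edge inclusive, so eGFR exactly 30 falls in the 40 mg band.
Doses are assessed per administration (each dose is classified), with the
per-day total reading available by summing assessments within a day.
Doses given before any eGFR is available are ineligible rather than
incorrect. An encounter is fully compliant when it has at least one correct
dose and no incorrect ones.

## Outcome metrics

* **Admission stage**: the first combined evaluation within 6 h of
  admission; encounters with no evaluation in that window have an *unknown*
  admission stage, are flagged, and count as not-admitted-with-AKI in cohort
  tallies (the operational definition used with chart data, where
  pre-admission measurements are unavailable).
* **Discharge stage**: the combined stage at the time of the last urine or
  creatinine measurement.
* **Per-day maxima** (days 1–5): the maximum combined stage evaluated in
  each 24-h window, carrying the last value into update-free windows —
  the combined stage is a state, not an impulse (configurable off). Days
  starting after discharge are absent. Encounters admitted with AKI are
  excluded from per-day prevalence tables.
* **Progression flags**: an encounter progressed from stage 1 when any
  consecutive pair of combined evaluations moves from 1 to a higher stage
  (1 → 3 counts); likewise 2 → 3. The flags are per-encounter: repeated
  episodes count once.
* **Time to AKI**: the ICU day (ceiling of hours/24) of the first nonzero
  combined evaluation; encounters discharged AKI-free are censored at their
  discharge day. The AKI-free curve is the discrete daily product-limit
  estimate, computed with `survival::survfit()` and checked against a
  hand-computed product-limit table in the tests. Whether admission-AKI
  encounters enter as day-1 events is configurable; by default they are
  excluded from the curve.
* **Cohort table**: every proportion is reported with its numerator and
  denominator. Admission/development/discharge proportions use all
  encounters; maximum-stage and any-AKI prevalences use encounters not
  admitted with AKI (the denominator that reproduces the published
  percentages); progression rates use encounters that ever reached the
  originating stage. Published cohort tables are ambiguous about the
  maximum-stage denominator, which is why both numbers are always printed.

## Comparison statistics

The "binomial proportions test" used for cohort comparisons is implemented
as the pooled two-sample z test (two-sided normal p-value); this is the
reading that reproduces the published p-values of the cohort table to their
printed precision. A chi-square-with-continuity variant is available through
`prop.test` directly. Demographic comparisons from published summary rows
use the summary-statistic Student t test (pooled variance by default, Welch
optional). The design power calculation is a Monte-Carlo simulation of the
one-tailed Fisher exact test (hypergeometric tail, vectorised, identical to
`fisher.test`), at the study's parameters: baseline progression rate,
relative reduction, encounters per arm, α = 0.04. Under a zero effect the
simulated rejection rate sits at the nominal level. The package does not
claim to reproduce the published power value of 0.86: the sentence reporting
it does not state the baseline rate or the denominator population, so the
simulation takes explicit rates instead. The exact-test agreement between
the z test and a full pooled-binomial enumeration is verified in the z
test's validity regime (all cells at least 5, significance range); outside
it the normal approximation genuinely deviates, which is a property of the
test, not of the implementation.

## The synthetic cohort generator

No clinical data are distributed with the study the package operationalises,
so the generator is a first-class module: it emulates two ICU populations
with *known latent truth* so that every downstream module can be tested
end-to-end.

* **Demographics and stays** follow the published cohort overview: ~42%
  general-ICU encounters, age 63.6 (14.5) years clamped to 18–90, 32%
  female, 1.3% Black, admission weight log-normal with mean 81 and SD 20 kg,
  and ICU length of stay log-normal targeting mean 5.8 and SD 6.7 days.
  Stays are rounded **up** to whole days so every latent stage day is fully
  charted and detectable within the stay; the realised mean stay is
  therefore slightly above the target, which none of the tested quantities
  depend on.
* **Latent stages** evolve on a daily clock: a per-day onset hazard starts a
  stage-1 episode (front-loaded in the cardiac ICU, where the postoperative
  insult falls in the first day or two; spread across the stay in the
  general ICU); a drawn progression flag (default probability 0.42,
  control-like) escalates the episode to stage 2 after its stage-1 dwell
  time, and a second flag (default 0.213) on to stage 3. By default stages
  are **non-decreasing within the stay**. This is a deliberate departure
  from real cohorts (where many encounters recover before discharge, so
  discharged-with-AKI counts fall below developed-AKI counts): the trailing
  UO windows carry the previous day's low output into a recovery day, so a
  generator with in-stay recovery cannot make the emitted chart events agree
  with the latent path at day granularity. With monotone paths the noise-free
  round trip is exact, which is what the fidelity tests require.
* **Emissions** are hourly and, in noise-free mode (the default), satisfy
  exactly the AKIN criterion of the latent stage. Stage-1 days alternate
  6-h blocks at 0.7 and 0.4 mL/kg/h, so the trailing 6-h mean dips below
  0.5 without dragging the 12-h mean under the stage-2 threshold; stage-2
  days run at 0.4 (12-h mean below 0.5, 24-h mean above 0.3); stage-3 days
  at 0.25. A configurable fraction of episodes (default 30%) is expressed
  through creatinine instead, at ratios 1.6/2.5/3.5 of the baseline the
  engine will resolve — the charted baseline when present, the MDRD estimate
  otherwise — so recovery is exact in both channels. Truncated-normal jitter
  is available for both channels and defaults to off.
* **Dosing** is daily: an eGFR computed from the current creatinine is
  charted before each dose; with the configured error probability (default
  1.72%, control-like) the dose exceeds the recommendation for that eGFR,
  otherwise it equals it (withheld when the recommendation is zero).
* **Determinism**: generation is a pure function of the configuration,
  seed included; the same configuration yields byte-identical CSVs. A
  two-phase study derives independent phase seeds from one master seed.

Two things the generator deliberately does **not** emulate: in-stay recovery
(above), and the censoring interaction between late onsets and progression.
An episode that starts on the last ICU day cannot progress, so under
hazard-mode onsets the *realised* progression rate among stage-1 encounters
is lower than the configured propensity — exactly as discharge censors
progression in real cohorts. Parameter-recovery tests therefore use the
`onset_mode = "all_day1"` design with stays of at least two days, where
realisation is guaranteed and the measured progression proportion is an
unbiased binomial draw at the configured probability. There is also no
missing-not-at-random charting model and no creatinine-kinetics ODE; passing
round-trip tests show the engine recovers trajectories whose emissions obey
the staging criteria, not that it is robust to adversarial real-world
charting.

## Problem sizes and runtime choices

The test suite exercises: oracle agreement of the UO engine against a
brute-force window enumeration on 500 random 72-h grids (plus 120 in the
unit tests); monotonicity and dominance suites of 60–80 randomised cases
each; parameter recovery at 1000 stage-1 encounters per arm and ~20,000
assessed doses per arm; null calibration of the two-phase comparison over
150 master seeds at 120 encounters per arm; and power-simulation calibration
at 10,000 replicates. These sizes give exact binomial 95% confidence
intervals a few percentage points wide — tight enough to detect
implementation bias — while keeping the full suite in the low minutes on a
single CPU.

## Known limitations

* The published study's cohort-level staging outputs are not reproducible
  without its (non-deposited) clinical data; the package reproduces the
  printed worked-example arithmetic and p-values exactly, and validates the
  engine by property-based testing and synthetic round trips instead.
* KDIGO's 7-day creatinine window and fluid-corrected creatinine are out of
  scope; staging is AKIN throughout.
* RRT encounters are excluded from staging analyses rather than displayed as
  stage 3; the display rule belongs to the bedside tool, not the analysis.
* The dose table ships with the three reconstructed default bands; sites
  with different protocols must supply their own table.
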