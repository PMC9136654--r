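---
title: "Measuring EHR work outside scheduled clinic hours from access logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EHR work outside scheduled clinic hours from access logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic health record (EHR) systems keep an audit log: a time-stamped
record of every discrete user action (chart views, note edits, order entry,
inbox work, log-ins). Clinicians widely report that EHR work spills into
evenings and weekends, but most quantitative estimates classify "after
hours" work by fixed clock times (say, before 8 AM or after 6 PM). That
misclassifies physicians whose clinics genuinely run in the evening or
only part of the week. `ehrwow` instead anchors the during/outside split to
each physician's **actual scheduled patient visits**: scheduled clinic
hours on a day are the union of all visit intervals padded by a margin
(default 30 minutes) that captures preparatory and closing work, and
everything else — gaps between sessions, evenings, weekends — is work
outside scheduled clinic hours.

The pipeline takes four tables: raw access-log events (user, timestamp,
action code), scheduled visits (physician, start, end), a physician roster
(demographics, FTE, clinical FTE, employment status), and an action-code
category map. It produces per-physician-per-workday time summaries, action
category tables, top-action tables, a high-user subgroup, and crossed
random-effects models of daily and weekly EHR hours.

## Estimating access time

Audit logs record instants, not durations. Per-action access time is
estimated by the standard inter-event-gap rule: an action's duration is the
gap to the *same user's* next logged action; each user's final event gets
duration zero. Deltas are computed across day boundaries first, and idle
time is then removed: any action spanning more than the idle cutoff
(default 15 minutes, configurable via `filter_idle(cutoff_min=)`) is
treated as time away from the terminal. Removal is deliberately strict —
a gap of exactly 15 minutes is retained — because the rule is stated as
"more than". Overnight gaps are removed by this same cutoff, which is why
no special day-boundary handling is needed.

Two readings of "removed" are supported. The default drops the idle action
from both time totals and frequency counts; `idle_policy = "zero_duration"`
instead keeps the event at zero duration so frequency surfaces still count
it. The removal tally is always reported in the run manifest.

## Windows and segmentation

`build_clinic_windows()` forms, per physician-day, the union of
`[visit_start - margin, visit_end + margin)` with touching or overlapping
expansions merged, so back-to-back visits produce one contiguous window.
Intervals are **half-open**: an event at a window's exact end is outside.
This convention removes any double counting at boundaries and makes the
during/outside decomposition exact.

`segment_actions()` intersects each action's occupancy interval
`[t, t + duration)` with the physician's windows. The default
`straddle = "split"` policy divides a boundary-straddling action's
duration proportionally by clock time, so `during + outside = duration`
holds to machine precision for every action; `straddle = "start"` assigns
the whole duration to the side containing the start timestamp. Frequency
counts always use the start-timestamp side (the *primary segment*), so
counts stay integers under either policy. The split implementation uses a
per-physician cumulative in-window time function evaluated with
`findInterval()`, and the test suite checks it against an independent
brute-force oracle that assigns every whole second by point-in-interval
testing.

A window generated by an evening clinic may cross midnight; it belongs to
the date of its earliest generating visit, which keeps day assignment
deterministic.

## Action taxonomy

Actions carry two labels. The *clinical* category is the six-way scheme:
reviewing data and reports; creating and authenticating documentation;
inbox and communication tasks; entering and authenticating orders; log-in;
logout. The *conceptual* category is the four-way projection — data review,
data entry (documentation and orders), data transmission (inbox), other
(log-in/logout) — and is fixed rather than user-overridable: a shared
conceptual layer is only useful for cross-study comparison if everyone
projects the same way. Unmapped action codes are a hard error by default;
`unmapped = "bucket"` downgrades them to an explicit `uncategorized`
bucket that is reported separately, never silently folded into a clinical
category.

The package ships no real vendor mapping (none is public); the default
290-code vocabulary from `default_action_map()` is synthetic, with
161/64/34/19/6/6 codes per category. The 12 general codes' split between
log-in and logout (6/6) is a synthetic choice.

## Aggregation conventions

A **physician workday** is any (physician, date) with at least one retained
event or at least one scheduled visit; days with neither do not appear.
The rule is configurable (`workday = "either" | "events" | "visits"`)
because the denominator definition materially changes per-workday averages
when there is weekend activity; `"either"` is the default because it ties
the denominator to observed activity of either kind.

Cohort means and SDs average each physician over their workdays first and
then summarize across physicians, matching the "per physician per workday"
reading; the category and top-action tables instead pool hours over all
physician-workdays, which is the natural convention for tables whose rows
must be additive. Printed surfaces follow fixed rounding rules — hours to
2 decimals with integer column percents in the category table, integer
frequencies and 1-decimal minutes in the top-action table — and **totals
are computed on unrounded values and then rounded**, so a rounded column
can disagree with its printed total by one unit in the last place. That is
the defensible convention, and the tests pin it down.

Administrative time is a fixed fraction (default 11%) of nominal clinical
hours divided by the number of physician-workdays. Cohort eligibility
excludes contingent employment, zero clinical FTE, and physicians with no
scheduled visits in the period, tallied by reason. High users are
physicians whose per-workday mean outside-hours strictly exceed 1.5 h.

## Mixed models

`fit_ehr_mixed()` fits, by REML via `lme4::lmer()`, one of three outcomes
— daily (or ISO-weekly) EHR hours during, outside, or in total — on age
(years), gender (indicator for female, reference male; the coding is a
documented choice, not a claim about any particular study), and clinical
FTE, with crossed random intercepts for provider and day (week under
weekly aggregation). The outside-hours model additionally adjusts for EHR
time during clinic hours, entered in minutes; the other two models never
include it.

The model-fit partition reported is additive by construction:

* `r2_fixed` = var(fixed linear predictor) / total,
* `r2_random` = (provider variance + day variance) / total,
* `r2_total` = their sum,

where total = var(fixed predictor) + provider + day + residual variance.
This is the standard marginal/conditional-style variance partition; the
partition is invariant to affine rescaling of the outcome, and the suite
verifies both additivity (within 0.1 percentage point) and the invariance.
Singular fits (a variance component at the boundary zero) are flagged, not
errors; a constant outcome returns a degenerate result rather than calling
the optimizer. A residual-normality diagnostic (`normality_check()`)
reports skewness, excess kurtosis, and a quantile comparison and recommends
a `log1p` transform when skewness exceeds 1; the default transform is
`none` and nothing is ever transformed silently, because coefficients on
the original hour/minute scale are the quantity of interest.

## The synthetic cohort generator

No raw hospital audit logs can be shipped, so `simulate_cohort()`
generates a full synthetic study with known ground truth. Its defaults are
the study conditions the package targets, chosen once:

* 56 physicians over the weekdays of September 2019, holding clinic on a
  given weekday with probability 0.91 (≈19 clinic days each, ≈1070
  physician-days);
* 9 twenty-minute visits per half-day session (08:30–11:30 and
  13:30–16:30), i.e. 6 scheduled hours per clinic day, giving 8 hours of
  window capacity once 30-minute margins are added;
* per-workday during-hours budgets with cohort mean 4.4 h, decomposed into
  a between-physician SD of 1.8 h and a day-level SD of 0.87 h (their
  squares summing to the 2.0 h per-workday SD); outside-hours budgets with
  mean 0.8 h split 0.7/0.39 the same way, **floored at zero at both
  levels** — the floor yields a realistic point mass of physicians who
  never use the EHR outside clinic hours;
* log-normal inter-event gaps with mean 13 s (so a month produces on the
  order of 1.5 million events), renormalized within each block so gaps sum
  exactly to the day's budget, and capped at the idle cutoff;
* occasional injected idle gaps (rate 0.1 per clinic day) inside a window,
  which the idle filter must remove at the cost of one ordinary gap — the
  generator guarantees each day's budgets are recoverable within one
  event-gap of slack;
* evening activity from 18:00 on clinic days and weekend activity with
  probability 0.1 per physician-weekend-day, giving the evening/weekend
  tail; within-category code frequencies follow a Zipf(1) profile so that
  top-action tables have realistic skew.

Ground truth (per-day true budgets, per-physician latent means, cohort
bookkeeping) is written to a sidecar JSON, never into the observed CSVs.
Identical seeds give byte-identical files.

What the generator does **not** emulate: clinical content, visit-level
no-shows or walk-ins, within-session pacing structure, device or module
mix, secular trends across the month, and shared calendar-day shocks
(there is no day random effect in the event generator, so pipeline-fitted
day variance components on simulated data sit near zero and the fit is
legitimately singular there). Passing recovery tests therefore demonstrate
that the pipeline measures what the generator encodes — time budgets,
category mix, schedule structure — not that real audit logs satisfy those
assumptions. `simulate_model_data()` complements this by generating daily
summaries directly from the mixed-model data-generating process (known
coefficients, provider SD 0.8, day SD 0.24 in the default recovery
design), which is the right oracle for the model-fitting layer.

## Numerical choices and degenerate inputs

* Timestamps are a single zone-naive local clinic clock at second
  resolution; ties are allowed and keep file order.
* During/outside splits are exact real arithmetic on seconds; conservation
  is asserted at 1e-9 s per action and 1e-6 h globally.
* Top-action ties break by frequency, then total minutes, then
  lexicographic action code, so outputs are deterministic.
* Empty inputs (no visits on a day, empty action streams, all-below
  threshold subgroups) return empty-but-well-formed results, not errors;
  contract violations (unsorted events, end before start, cFTE above FTE,
  unmapped codes under the strict policy) are hard errors with row
  context.
* Budgets that exceed window capacity are truncated with a warning — with
  the default 8-hour capacity this affects roughly the top 3% of drawn
  during-budgets.

## Problem sizes used by the test suite

Unit tests run on 6-physician months with 60-second mean gaps (tens of
thousands of events, a few seconds each). The end-to-end acceptance
properties use ten full default months (56 physicians, ~1.5 M events each)
for cohort-mean recovery, ten simulated model datasets (56 providers × 19
days) for coefficient and variance-component recovery, and at least 1000
randomized window/action instances for oracle equivalence of the interval
decomposition. These sizes were chosen so the whole suite exercises the
paper-scale design while remaining comfortable to run on a laptop.

## Known limitations

Inter-event gaps are an upper-bound proxy for active use: the final action
before a break absorbs the idle threshold's worth of ambiguity, and no
keystroke- or focus-level inference is attempted. The workday denominator
is a modelling choice with visible consequences (documented above and
configurable). The crossed random-intercept structure assumes exchangeable
day shocks and no autocorrelation; random slopes and serial structures are
out of scope. The R² partition estimator is one standard choice among
several in the mixed-model literature; results should be compared across
studies only under the same definition.
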