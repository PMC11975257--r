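---
title: "Pre-cycle decision support: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-cycle decision support: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleguard)
```

## The problem

Prescribing the next cycle of a cytotoxic chemotherapy regimen is a
gating decision: it may proceed only if bone-marrow, liver and kidney
function (blood counts, transaminases, bilirubin, creatinine) are
inside safety limits and treatment side effects have not become
severe. In most units this pre-cycle check is a manual, phone-based
process. `cycleguard` models the knowledge-based alternative: symptoms
arrive as electronic patient-reported outcomes (ePROs) graded 0-4 on
the NCI-CTCAE scale, laboratory panels arrive from the hospital
system, and explicit IF-THEN rules combine them into a three-tier
recommendation — tier 1 "go" (fully automated clearance), tier 2
"evaluate" (a nurse or physician must look), tier 3 "postpone" (labs
unsafe; the infusion moves and data collection is re-programmed).

Because the rules are explicit rather than learned, every decision is
reproducible and auditable: the engine is a pure function of one cycle
record and one configuration, and each recommendation carries
machine-readable rationale codes plus any care-team override alongside
the original engine output.

## The decision model

For a cycle planned on date $d$ and freshness window $a$ days
(default $a = 3$), an observation made on date $t$ is *fresh* iff
$0 \le d - t \le a$ in whole days. Days are calendar days with no
time-of-day component, because the clinical rule is stated in days;
future-dated observations are never fresh, since the decision must
rest on pre-infusion data.

The engine evaluates, in precedence order:

1. panel present, fresh and out of range $\rightarrow$ tier 3
   (`LABS_OUT_OF_RANGE`);
2. panel absent, incomplete or stale $\rightarrow$ tier 2
   (`LABS_MISSING` / `LABS_STALE`);
3. questionnaire absent or stale $\rightarrow$ tier 2 (`EPRO_MISSING`
   / `EPRO_STALE`);
4. any symptom at grade $\ge 2$ and above its baseline grade
   $\rightarrow$ tier 2 (`SYMPTOM_GE2_ABOVE_BASELINE`);
5. otherwise tier 1 (`ALL_CLEAR`).

The first matching rule fixes the tier; the rationale nevertheless
records every condition that held, so a tier-3 decision on a cycle
that also lacked a questionnaire shows both codes.

Two modelling choices deserve justification:

* **Lab failure precedes missing data.** A cycle with out-of-range
  labs is postponed whether or not its questionnaire was completed.
  This makes the cohort-level tier-3 count identically equal to the
  count of lab-failing cycles — the consistency property asserted by
  the test suite — and reflects the clinical reality that no symptom
  review can clear an unsafe blood count.
* **Missing or incomplete labs are tier 2, not tier 3.** Absence of
  evidence routes to a human, not to an automatic postponement; only a
  measured out-of-range value postpones.

### Reference ranges

Screening is an inclusive interval test per analyte: a value exactly
on a bound is in range, the conventional reading of clinical reference
intervals. Units are declared in configuration and assumed consistent
between ranges and panels; no conversion is attempted. The shipped
default bounds (`default_reference_ranges()`,
`inst/extdata/default-config.yaml`) are illustrative standard adult
values with a chemotherapy-style thrombocyte floor of 100×10⁹/L; real
deployments must substitute the limits mandated by the regimen's
summary of product characteristics and local practice.

### Baselines and the symptom rule

A symptom contributes to tier 2 only if it is at grade ≥ 2 *and not
already at baseline*. The default reading (`grade_exceeds`) flags a
symptom whose current grade strictly exceeds its baseline grade, so
chronic grade-2 neuropathy does not repeatedly trigger evaluation but
a worsening from 2 to 4 does. The alternative absolute-exemption
reading — a symptom at grade ≥ 2 at baseline never flags again — is
available via `baseline_exemption = "absolute"`; we default to
`grade_exceeds` because it is the conservative choice for patient
safety.

"Baseline" itself is policy: by default a record without an explicit
baseline questionnaire is decided against the patient's earliest
completed questionnaire on record (`first_questionnaire`), which
matches a pre-treatment intake questionnaire when one exists; an
explicit per-record baseline always wins, and the `explicit` policy
disables the fallback entirely.

### The urgency algorithm

Independently of tier assignment, `detect_alerts()` raises an alert
for any symptom at grade ≥ 3 (`GRADE_GE3`) and for any symptom that
was grade 0 in the previous questionnaire and is grade 2 now
(`RISE_FROM_0`). At most one alert fires per symptom per
questionnaire; with no previous questionnaire there is no basis for a
"rise", so only `GRADE_GE3` can fire — first-contact grade-2 symptoms
are surfaced through the tier-2 pathway instead. The literal
grade-0-to-2 reading is the default; a configurable variant
(`any_rise_ge2`) alerts on any rise of at least two grades. Alert
presence is monotone in the current grade, a property the tests check
exhaustively over all 25 (previous, current) grade pairs.

## Scheduling

`schedule_cycle()` places one questionnaire send and one laboratory
collection before each planned infusion (defaults: 3 and 1 days of
lead; the real lead times of a deployment are not knowable in general
and are configuration). `on_decision()` is the state machine: tier 1
confirms the timetable to the patient, tier 2 emits no automatic
events because the yellow pathway is human, tier 3 moves the infusion
by `postpone_delay_days` (default 7, the conventional one-week
chemotherapy delay unit) and re-enters `schedule_cycle()` for the new
date, so no cycle can reach decision time without scheduled data
collection. Postponement is re-entrant: $n$ consecutive tier-3
decisions move the date by exactly $n$ × the delay.

Ambulatory-pump regimens create two reservations at once (infusion
plus pump removal a couple of days later), which would naively double
the questionnaire schedule. `merge_reservations()` clusters a
patient's reservations transitively — any reservation within
`reservation_merge_window_days` (default 3) of the previous one joins
its cluster — and only cluster heads generate collection events.
Chain-merging is idempotent and was chosen over fixed-anchor windows
because it handles a pump-removal pair and a longer maintenance chain
with the same rule.

## The synthetic cohort generator

`simulate_cohort()` emulates the observation process the engine
assumes, per cycle: a fresh laboratory panel that is out of range with
probability `p_lab_out_of_range` (realized by displacing one uniformly
chosen violable analyte beyond its bound); a questionnaire completed
with probability `p_questionnaire_completed`, back-dated beyond the
freshness window with probability `p_stale_given_completed`, and
graded by drawing each symptom independently from a categorical
distribution over grades 0-4.

The defaults are the conditions of the feasibility study this
workflow comes from: 43 patients, 6-10 cycles each (about eight on
average), completion probability 0.773 (262/339), lab-failure
probability 0.327 (111/339), and grade distributions calibrated so
that fatigue and peripheral sensory neuropathy are reported
(grade ≥ 1) with probabilities 0.529 and 0.509; other symptoms default
to 0.15, and non-zero mass is split 70/24/5/1 over grades 1-4,
reflecting that most reported symptoms are mild. The study does not
decompose its 77 unavailable questionnaires into never-completed
versus stale, so staleness defaults to 0 and is opt-in. Given a seed
the generator is exactly reproducible, and it restores the caller's
RNG state.

What the simulator deliberately does not model: symptom correlation
within a questionnaire (grades are drawn independently; real fatigue
and appetite loss co-occur), within-patient persistence of symptoms
across cycles, disease progression, and any dependence of lab failure
on prior postponements. Passing recovery tests therefore shows the
pipeline is statistically faithful to its own generative assumptions,
not that those assumptions capture real cohorts.

## The deterministic fixture

`build_echo_fixture()` reconstructs a 43-patient, 339-cycle cohort
whose marginals equal the study's published aggregate counts: 262
cycles with a fresh questionnaire, 221 of them with all grades ≤ 1;
228 cycles with labs in range; 843 completed questionnaires with
fatigue reported in 446 and neuropathy in 429; 137 individual
grade-3/4 symptom records of which 5 are diarrhea and 4 neuropathy.
It is a synthetic reconstruction from published aggregates, not
patient-level data.

The published marginals do not determine the joint distribution —
how questionnaire problems co-occur with lab failures. Writing $b$
for the number of grade-≥2 questionnaires sitting on lab-passing
cycles, consistency forces the lab-passing side to split into 145
clean + $b$ flagged + $(83-b)$ missing and the lab-failing side into
76 clean + $(41-b)$ flagged + $(b-6)$ missing, for any $b$ in 6..41.
The canonical fixture uses $b = 41$; under the engine's lab-first
precedence *every* admissible $b$ yields the same tier counts
145/83/111, which the test suite asserts for several splits. Two
published figures cannot be embedded simultaneously: 137 grade-3/4
records with diarrhea (5) and neuropathy (4) as the *most common*
contributors is arithmetically impossible, since the remaining 128
records spread over 14 other symptoms average more than 9 each. The
fixture preserves the counts (137/5/4) and spreads the remainder
evenly, sacrificing the ranking. Each patient's first questionnaire
is a pre-treatment baseline (all grades ≤ 1, nausea 0, dated before
every cycle), so the `first_questionnaire` baseline policy resolves
deterministically.

## Reporting and numerical choices

`performance()` recomputes the headline metrics from a decided log
using the same freshness primitive as the engine; `prevalence()`
counts a symptom as reported when its grade is ≥ 1, because a grade-0
entry denotes absence, with completed questionnaires as the
denominator and individual grade-3/4 records as the severe-symptom
denominator. All percentages are rounded half away from zero to one
decimal (base `round()` rounds half to even); the implementation
pre-rounds at 8 decimals so decimal halves stored just below .5 in
binary still round up, and the suite property-tests this against an
integer-arithmetic oracle. Degenerate inputs are defined, not
errors: an empty log yields a zero-cycle report with percentages
absent, an empty questionnaire pool an empty prevalence report, and
an absent panel an `INCOMPLETE` evaluation.

## Problem sizes

The test suite exercises the exhaustive oracles at their natural
sizes (25 grade pairs, 25 lab×ePRO states, all 3⁷ analyte-status
vectors) and statistical recovery on simulated cohorts of 1,200 and
5,000 cycles with three-standard-error bands; the fixture pipeline
runs the engine over all 339 records. These sizes were chosen so each
check is exact or statistically decisive while the whole suite stays
interactive.

## Known limitations

The package models the decision layer only: message delivery, EHR and
reservation-system interfaces, self-care advice content and dose
modification advice are out of scope. The symptom catalog defaults to
the 16 core chemotherapy symptoms but is configuration, as catalog
size varies between deployments. Units are trusted, not converted.
The fixture reproduces published aggregates; it cannot recover
patient-level structure (per-patient call burden, symptom
trajectories) that the aggregates do not determine.
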