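---
title: "Methods: the zone-of-control engine, reminder rules, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the zone-of-control engine, reminder rules, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airplan)
```

This vignette is the package's own account of the models and rules it
implements, the choices made where the design was genuinely open, and what
the test suite does and does not demonstrate.

## The control assessment

An assessment at time $t$ looks only at the trailing half-open window
$(t - w,\, t]$, with $w = 7$ days by default because the control criteria
it applies are weekly quantities. Journal entries in the window are reduced
by `aggregate_window()` to: distinct symptomatic calendar days, night
wakings, activity-limited days, total reliever doses, a danger-symptom
flag, and the most recent in-window peak flow. Counting *distinct local
calendar days* (in the patient's own timezone) rather than entries avoids
double-counting patients who journal more than once a day.

The symptom component maps this aggregate to a zone: red whenever
danger-level symptoms were reported (dominance, regardless of everything
else); otherwise green when daytime symptom days $< 4$/week, night wakings
$< 1$/week, reliever doses $\le 3$/week and no activity limitation; yellow
otherwise. These cut-offs follow the weekly control tables used in
guideline-based traffic-light plans; they are data, not code — every limit
is a `symptom_criteria()` field.

The peak-flow component bands the latest in-window measurement against
absolute thresholds. When the provider entered fractions (or none), they
resolve against the personal best $PB$ as green $\ge 0.90 \cdot PB$ and
red $< 0.60 \cdot PB$. Both entry modes are supported because deployments
differ in whether ranges arrive as absolute flows or percentages.
Lower bounds are *inclusive* — a flow at exactly 90% of personal best is
green — matching the "90% of personal best or better" phrasing of
guideline practice. A measurement older than the window never contributes.

The two components combine worst-of (red > yellow > green): the
safety-conservative rule, standard in action plans, under which a
reassuring symptom week cannot mask a falling peak flow. When *neither*
component exists — no in-window entries and no in-window peak flow — the
engine returns `insufficient` with `basis = "none"` rather than defaulting
to any zone. The explicit insufficient path matters: in real deployments a
substantial share of on-demand assessments happen on days without recent
journal data, and silently calling them green would be clinically wrong.
If the plan relies on peak flow (`requires_pef`) but thresholds cannot be
resolved, the assessment is likewise insufficient.

**Reset semantics.** The zone is dynamic: once the patient executes the
action plan, the entries that triggered it are consumed. `apply_reset()`
keeps only entries *strictly after* the latest reset instant at or before
the assessment time; the strict inequality expresses that the executed
plan consumes the triggering entries themselves.

**Good days.** A journaled day is a *good day* only if all four symptom
flags are false **and** reliever doses are zero. Whether a reliever-only
day counts as symptomatic was an open call; we count it as an episode day
because reliever use indicates symptoms, and we state it here because
published good-day counts elsewhere may use the looser definition.

## Reminder rules

Three email kinds, all at the profile's reminder time (19:00 local by
default, per-profile IANA timezone, stored timestamps UTC):

* **welcome** — once, at enrollment;
* **adherence** — daily while at least one controller medication is
  prescribed, uncapped and independent of platform use;
* **check_in** — on each day $D$ such that the patient logged in on none
  of the 7 local calendar days ending at $D$ and no check-in was sent in
  those 7 days.

The repeat cadence of check-ins is not specified anywhere authoritative;
re-sending after every further 7 days of silence is our choice, consistent
with the uncapped spirit of the adherence rule, and it gives the closed
form $1 + D + \lfloor D/7 \rfloor$ emails over $D$ fully inactive days,
which the acceptance suite verifies for $D = 1..60$. The calendar-day
reading of "7 days without access" (rather than 7×24 h from the last
login instant) is what makes that closed form exact.

Message bodies rotate uniformly over the pool *excluding the immediately
previous body* — "random" rotation plus the fatigue-mitigation intent.
Message ids are 1-based indexes into the pool, the natural R convention.
Whether a check-in should suppress that day's adherence email is unstated;
they are independent here.

## AQHI banding

Health Canada's published categories: 1–3 low, 4–6 moderate, 7–10 high,
above 10 very high; a total monotone step function. Band messages are
configuration with asthma-oriented placeholder defaults; the authoritative
texts belong to the deployment, not the package. Readings come from a
local CSV, a deliberate stub for a live feed so nothing in the package
needs a network.

## The event log and its analytics conventions

Every analytic runs off the append-only typed event log. Conventions that
shape the numbers:

* **Intervals are half-open** $[s, e)$; weeks are numbered 1–52 from each
  patient's enrollment instant (patient clocks, not calendar weeks), and
  months are the twelve 30⅓-day tiles of the 52-week year.
* **pppw** divides by cohort size × the full 52 weeks regardless of
  individual attrition (an observed-time variant would inflate late-study
  rates as the denominator shrinks); rates display at 2 decimals,
  percentages at 1–2.
* **Raw event counting**: multiple same-day accesses are distinct logins;
  no session de-duplication is attempted because none is defined.
* The rank-sum comparison of weeks-with-login between subgroups uses the
  exact null when the smaller group has ≤ 10 observations and no ties
  (verified against full enumeration of rank partitions in the acceptance
  suite), else the normal approximation with tie and continuity
  correction.
* SUS scoring is the standard instrument formula
  $2.5\,[\sum_{odd}(r-1) + \sum_{even}(5-r)]$; Likert items bucket 1–2 /
  3 / 4–5 over non-missing responses.

## The synthetic cohort

`simulate_cohort()` exists so that every pipeline stage — engine, planner,
log, analytics — can be exercised end-to-end at realistic scale without
patient data. It emulates, structurally:

* **Engagement decay with a floor.** A patient is *active* in week $w$
  with probability $p_w = p_\infty + (p_0 - p_\infty)e^{-\lambda w}$. The
  weekly-probability form alone cannot produce several logins per week, so
  the model is two-level: within an active week each day brings a
  spontaneous login with probability `active_daily_login`. Defaults
  $p_0 = 0.95$, $p_\infty = 0.55$, $\lambda = 0.30$/week,
  `active_daily_login` $= 0.40$ place week-4 weekly-active activity near
  two-thirds of the cohort with roughly 3 logins pppw — the engagement
  regime of a deployed, mostly-satisfied cohort with the characteristic
  rapid early fall.
* **Reminder response**: on adherence-email days of active weeks, an
  extra login lands in the two hours after 19:00 with probability 0.25,
  producing the evening spike in the hour histogram; 45% of spontaneous
  logins fall in a 05:00–10:00 morning block.
* **Surveillance effect**: login and reporting propensities are multiplied
  by 1.6 in the two enrollment-relative weeks ending at each scheduled
  visit (weeks 26 and 52), and a `clinic_visit` event is emitted.
* **Demographic texture**: 49/122 of patients are 50+, with a modest
  (×1.15) engagement advantage; a mean-1 gamma multiplier
  (`engagement_sd` = 0.5) individualizes within-week intensity and
  reporting propensity. The multiplier deliberately does **not** touch
  $p_w$, so the cohort-mean weekly-active curve keeps the three-parameter
  exponential shape that `fit_attrition_decay()` estimates.
* **Symptoms**: a two-state daily Markov chain (controlled/uncontrolled,
  stay probabilities 0.97/0.85, stationary ≈ 17% uncontrolled) drives
  symptom flags, reliever use, and peak flow
  ($PB \times$ state mean $0.95/0.72 \times (1 + N(0, 0.06))$). The
  per-state daily probabilities are set so journaled days split roughly
  2:1 good-to-episode, the signature of a mostly-controlled cohort.
* **Reporting given login**: journals 0.83, medication reports 0.10,
  peak-flow reports 0.30, on-demand zone checks 0.88 — ratios taken from
  the relative per-type event rates such platforms report. Zone
  calculations run the *real* engine on the simulated journals (including
  reset semantics: a yellow/red result is followed by plan execution with
  probability 0.25), so `insufficient` outcomes arise organically when a
  patient checks their zone without recent journal data. Emails come from
  the real planner run over each patient's simulated login history.

Reproducibility: one seed per cohort; per-patient substreams are derived
deterministically from (seed, patient index), so logs are bit-identical
across runs and independent of evaluation order.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: no seasonality or weekday structure; no
exacerbation clustering beyond the two-state chain; attrition is
memoryless given $p_w$ (no permanent dropout state, though the floor
mimics its aggregate effect); symptom state and engagement are
independent, whereas real patients journal *more* when unwell; no
measurement error in self-reports. The preset is a structural reference
point, not a claim to reproduce any particular cohort's patient-level
data, which is why tests assert qualitative bands (week-4 weekly-active in
[0.55, 0.80]; good:episode within ±50% of 2:1) rather than point values.

## Numerical and degenerate-input choices

* Threshold resolution is idempotent; resolved thresholds always satisfy
  green > yellow > 0 or error.
* Empty journal windows are valid (zero counts), but
  `classify_symptoms()` refuses an empty aggregate: with no data the
  symptom component does not exist, which is what the insufficient path
  encodes.
* `fit_attrition_decay()` minimizes least squares with L-BFGS-B under box
  constraints $p_0, p_\infty \in [0,1]$, $\lambda \in [0, 20]$, from five
  deterministic $\lambda$ starts (0.02–1) with data-driven $p_0$/$p_\infty$
  starts; a constant curve short-circuits to $\lambda = 0$ at the mean.
  On a noise-free curve the parameters are recovered to well under 1%.
* Ties in email ordering (same instant) break welcome < adherence <
  check-in; event logs sort by timestamp, then patient, then type.
* ISO-8601 UTC timestamps at second resolution everywhere; peak flows are
  rounded to 0.1 L/min in payloads so serialization round-trips are exact.

## Problem sizes in the test suite

The suite enumerates the full decision grid (8 symptom-day × 8
night-waking × 11 reliever × 2 severe × 18 peak-flow levels ≈ 25,000
assessments) against an independently written rule evaluator; property
checks use 120 randomized monotonicity probes and 30 reset probes; the
decay-recovery experiment uses a 1,000-patient login-only cohort over 52
weeks; serialization round-trips use 10,000 mixed events per format; the
end-to-end preset runs 123 patients × 52 weeks. These sizes keep the whole
suite around two minutes while leaving each check at full strength.

## Known limitations

The engine implements one guideline-style criteria table; deployments with
different control definitions must supply their own `symptom_criteria()`.
The insufficient rule is ours — field platforms differ in when they
decline to answer, and no published rule set pins it down. The reminder
planner models delivery, not receipt (no bounces, no read receipts). The
analytics assume complete logs; there is no imputation for patients with
partial observation. And the simulator's independence assumptions (above)
make it unsuitable for studying engagement–health interactions.
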